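Package: epiclone
Title: Clonal Dynamics of Mutant Progenitors in Interfollicular Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic and deterministic models of keratinocyte clonal
    dynamics in interfollicular epidermis. Implements the single-progenitor
    fate model (master-equation solutions, closed-form moments and exact
    Gillespie simulation), maximum-likelihood inference of fate imbalance
    from clone-size time courses, a mean-field two-genotype tissue model
    with a mechanistic hypothesis scan, an H2B-GFP label-dilution
    division-rate model and fit, a non-spatial Moran simulator of clonal
    competition under ongoing mutagenesis, and the grouped
    Benjamini-Hochberg post-filtering of ultra-deep targeted sequencing
    variant calls with burden and mutational-spectrum summaries. A
    synthetic-data generator produces every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    deSolve,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
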