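---
title: "Models and methods: clonal dynamics of mutant epidermal progenitors"
author: "epiclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: clonal dynamics of mutant epidermal progenitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclone)
```

## The single-progenitor model

Interfollicular epidermis is maintained by one functionally equivalent
population of basal progenitor cells.  A progenitor divides at rate
$\lambda$ (per week) and the outcome of each division is stochastic: two
progenitors (PP), two post-mitotic differentiating basal cells (DD), or
one of each (PD).  In homeostasis the symmetric outcomes balance,
$p_{PP} = p_{DD} = r$, so the average division produces one progenitor
and one differentiating daughter and most labelled clones are eventually
lost by differentiation.  Differentiated basal cells stratify into the
suprabasal layer at rate $\Gamma$ and suprabasal cells are shed at rate
$\mu$.

A mutation that tilts fate is expressed through a single imbalance
parameter $\Delta$:
$$p_{PP} = r + \Delta/2, \qquad p_{DD} = r - \Delta/2, \qquad
  p_{PD} = 1 - 2r.$$
This parameterisation was chosen because it is minimal and invertible:
$\Delta = 0$ is exactly the balanced model, $\Delta$ alone measures the
excess of duplicating over differentiating divisions, and $r$ retains its
homeostatic meaning.  The expected progenitor number of a clone obeys
$E[n_p](t) = n_p(0)\,e^{\lambda\Delta t}$, a martingale when
$\Delta = 0$.

### Defaults and units

Time is measured in weeks throughout; explicit converters
(`weeks_to_days()` and friends) exist instead of implicit unit handling.
The package defaults are $r = 0.25$, $\lambda = 1.2$/week,
$\Gamma = 3$/week, $\mu = 1$/week.  These are *this package's* choice of
a realistic operating point for mouse dorsal epidermis, on the scale
reported by lineage-tracing studies of that tissue (division roughly
weekly, differentiated basal residence of a few days, suprabasal transit
of about a week); they are exposed everywhere as arguments and in
key-value config files, and nothing in the inference machinery depends on
them.

### Master-equation solution

`clone_size_pmf()` solves the forward master equation of the clone state
$(n_p, n_d)$ on the triangle $n_p + n_d \le n_{\max}$.  Two numerical
choices matter:

* **Lumped boundary.**  Probability flux that would leave the truncation
  is collected in one absorbing boundary state whose mass is reported per
  output time.  Truncation error is therefore observable, and callers
  (including the likelihood, below) can treat "size $> n_{\max}$" as a
  censored category instead of silently losing mass.
* **Uniformization.**  The truncated chain is autonomous and linear, so
  the transient solution is computed by uniformization
  ($p(t)^\top = \sum_k \mathrm{Pois}(k;\Lambda t)\, p_0^\top P^k$ with
  $P = I + Q/\Lambda$), with the Poisson tail truncated below a
  configurable tolerance (`tol`, default $10^{-10}$).  This is exact to
  that tolerance, has no stiffness issues even though pmf entries span
  many orders of magnitude, and yields all requested timepoints in a
  single pass.  Mass conservation to $10^{-6}$ is asserted in the test
  suite.

The suprabasal count is marginalised out of the pmf (it does not feed
back on basal dynamics and would cube the state space); the Gillespie
path simulator (`simulate_clone()`, C++ under the hood, driven by R's
RNG so `set.seed()` gives bit-reproducible paths) tracks all three
compartments.

## Likelihood and inference

Wholemount scoring only records clones with at least one basal cell, so
the likelihood of a clone table conditions on detection:
$$\mathcal{L} = \prod_i
  P(\text{basal size} = s_i \mid \text{size} \ge s_{\min}, t_i).$$
Observed sizes beyond $n_{\max}$ contribute the censored boundary mass.
Suprabasal counts are deliberately not used in the likelihood (state-space
cost; they inform the tissue model instead), and the detection rule is an
argument (`detection_min`) because other conditioning conventions (e.g.
on persisting clones) are plausible.

For a single free parameter — the routine case, fitting $\Delta$ with the
other rates fixed — `fit_sp_params()` evaluates per-clone log-probabilities
on a grid over the optimiser bounds (default 41 points) and refines the
grid argmax with a local quadratic step.  Because bootstrap resampling of
clones only reweights the per-clone terms, every bootstrap replicate
reuses the same grid, making a 200-replicate confidence interval
essentially free after the one grid evaluation.  The quadratic refinement
error is $O(h^2)$ and, at the default grid step, far below the sampling
error of the designs considered here.  Fits with several free parameters
use multi-start L-BFGS-B and bootstrap by refitting.

`compare_models()` contrasts the balanced ($\Delta = 0$) and biased
($\Delta$ free) models by AIC, with the likelihood-ratio statistic also
reported; the $\chi^2_1$ reference is flagged as approximate because
$\Delta$ may sit on a bound.  AIC was chosen as the default rule because
the two models are nested with a one-parameter difference and the
comparison is used as a detector, not as a formal test.  For detecting a
*proliferative* bias the alternative is one-sided, and the recommended
spec bounds $\Delta$ to $[0, 0.5]$: on the boundary the null LR is a
half–half mixture of $0$ and $\chi^2_1$, so the AIC rule's false-positive
rate drops from $P(\chi^2_1 > 2) \approx 16\%$ to about 8%.  A two-sided
fit (bounds straddling 0) remains the right choice for estimating
$\Delta$ itself.

Recovery at the study scale (300 clones over 1.5, 3, 6 and 12 weeks,
checked in `test-acceptance.R`): the null design gives
$|\hat\Delta| < 0.05$, the $\Delta = 0.25$ design is covered by the
bootstrap interval in $\ge 90\%$ of seeds, and model preference has the
corresponding power and type-I behaviour.

## Mean-field tissue model

`simulate_mean_field()` integrates, per genotype,
$$\dot P = \lambda \Delta_{\mathrm{eff}} P, \qquad
  \dot D = \lambda (1 - \Delta_{\mathrm{eff}}) P - \Gamma D, \qquad
  \dot S = \Gamma D - \mu S,$$
with the wild type required to be homeostatic and initialised at its
fixed point.  An optional crowding feedback
$\Delta_{\mathrm{eff}} = \Delta \max(0,\, 1 - k\,(B/B_0 - 1))$ linearly
attenuates the fate bias as total basal density rises; this functional
form is an explicit modelling hypothesis of this package (the observation
it mirrors is that mutant expansion slows as density rises), not a
reproduced result.  The thickness proxy is the dimensionless
$1 + S_{\mathrm{tot}}/B_{\mathrm{tot}}$; mapping to micrometres is out of
scope.  The mutant's suprabasal compartment starts empty because labelled
cells reach it only by stratification.

`hypothesis_scan()` perturbs the mutant genotype in five named ways —
symmetric-division proportion change, stratification decrease, shedding
decrease, fate imbalance, and fate imbalance plus shedding decrease — and
scores three signatures as explicit inequalities with stated tolerances:

* **S1, progressive basal rise**: labelled basal fraction above its start
  *and* still growing over the second half of the course (this wording
  matters: a pure stratification change produces a bounded, saturating
  rise that the late-window test correctly rejects);
* **S2, suprabasal outruns basal**: labelled suprabasal fraction exceeds
  the labelled basal fraction at 12 weeks;
* **S3, thickening**: thickness proxy up by more than 2%.

The scan magnitudes ($\Delta = 0.2$, five-fold rate reductions,
$r \to 0.45$) are defaults of this package; the tested claim is *which
hypothesis class* reproduces the pattern, and only fate imbalance
combined with reduced shedding passes all three signatures.  Note that a
pure change in the symmetric-division proportion $r$ leaves all
mean-field equations unchanged (only $\lambda$, $\Delta$, $\Gamma$,
$\mu$ enter), which is itself the informative outcome: symmetric
proportion alone cannot generate any of the observed mean changes.

## H2B-GFP label dilution

After doxycycline withdrawal the histone label halves at each division,
so a cell that has divided $k$ times has log2 intensity
$i_0 - k + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$.  Divisions
follow a memoryless clock, $k \sim \mathrm{Poisson}(\lambda t)$, chosen
over fixed-interval divisions for consistency with the exponential clocks
of the clone model; the discrete-generation alternative is not separately
implemented because at the chase design used here the two are practically
indistinguishable through Gaussian intensity noise.  The mean log2
intensity declines exactly linearly with slope $-\lambda$, which
`fit_division_rate()` reports alongside the maximum-likelihood fit.

The likelihood is evaluated on a 512-bin histogram per chase time;
discretisation error is negligible against Monte-Carlo noise, and the
stratified cell bootstrap becomes a multinomial reweighting of bin
counts.  `test_rate_heterogeneity()` fits a two-rate mixture and reports
a likelihood-ratio statistic (df = 2, approximate at the boundary), and
`label_retaining_fraction()` quantifies slow-cycling subpopulations; for
homogeneous cycling the retained fraction follows the closed Poisson sum
$P(k \le k_{\mathrm{thr}})$.

## Clonal competition under mutagenesis

`run_competition()` implements a non-spatial Moran process at constant
progenitor number $N$: division events at total rate $\lambda N$, the
divider drawn with probability proportional to $c_i (1 + \Delta_i)$,
one uniformly chosen pre-division cell leaving the basal layer, and each
division founding a new clone with probability $\nu$, whose effect —
drawn from a DFE and added to the parental $\Delta$ (clipped to
$[-1, 1]$, clips counted) — keeps fitness commensurate with the fate
bias of the clone model.  The scheme's exact two-clone mean field is
$\dot f = \lambda s f(1-f)/(1 + s f)$, reducing to the replicator
equation for small $s$; both limits, and the exact absorbing-chain
fixation probabilities at $N \le 20$, are verified in the tests.

The default configuration emulates the long-term exposure experiment the
simulation addresses: induction of the transgenic clone at $f_0 = 1\%$
($N = 5000$), a single mutagen pulse pre-seeding 1% of cells with
DFE-drawn standing mutations, and chronic mutagenesis at
$\nu = 2\times10^{-3}$ per division with a DFE of 90% neutral effects and
a 10% exponential beneficial tail of mean 0.2 — competing driver clones
of strength comparable to the transgenic bias $\Delta_0 = 0.2$.  Under
these conditions the transgenic lineage typically expands for the first
12–16 weeks and is then progressively displaced by fitter background
clones, the qualitative pattern the module exists to capture;
`summarize_runs()` flags this rise-then-fall with explicit thresholds
(peak above twice the induced frequency, final below half the peak).
A weaker mutation supply (e.g. a beneficial tail an order of magnitude
smaller) lets the transgenic lineage fix instead — the same simulator
covers both regimes, and the choice is config, not code.

## Variant post-filtering

`run_filter_pipeline()` applies, in order: removal of variants present in
both paired biopsies of a mouse (somatic clones should not span distant
biopsies), Benjamini–Hochberg adjustment computed independently per mouse
with survivors at $q < 0.1$, and a requirement of at least one supporting
read on each strand.  The order is part of the contract — removing shared
variants first changes the BH families — and the attrition report makes
each stage's effect explicit.  The BH step-up is implemented in the
package (sorted $m\,p_{(j)}/j$ with running-minimum monotonicity) so that
`stats::p.adjust` can serve as an independent oracle in the tests rather
than as the implementation.  Grouping "per mouse" pools both biopsies of
a mouse into one family (the closest reading of per-mouse correction); a
per-biopsy alternative is selectable in `filter_config()`.  Burden is
variants per mm² at the default 16 mm² biopsy area, and the spectrum
collapses substitutions to the pyrimidine context before computing the
C>T fraction.  Strand counts are assumed deduplicated upstream.

## Synthetic data and what the tests do (and do not) show

`study_design()` + the `gen_*` generators produce every input with known
ground truth: clone tables at the published sampling times and clone
counts per timepoint, dilution chases, and paired-biopsy variant tables
whose planted classes (true somatic, shared germline-like, large-p
artifact, single-strand artifact) are placed far from the decision
boundaries so the surviving set is known by construction.  Bundles are
byte-identical under a fixed master seed.

The generators emulate the *statistical structure* of the study's data —
stochastic fate, detection-conditioned sampling, label halving with
multiplicative noise, paired biopsies with contamination — not its
biological messiness: no spatial clone fusion (the reason long-term
clonal data are not fitted), no segmentation error, no sequencing-depth
variation, no real mutational context beyond the C>T excess.  Passing
tests therefore demonstrate that the estimators and filters are correct
and well-calibrated on data generated by their own model class, not that
the model is true of real epidermis.

### Problem sizes

The acceptance-style checks run at: $10^5$ Gillespie paths per parameter
set (six sets) for the solver cross-check; 20 seeds of 300 clones by four
timepoints for fate-bias recovery; 20 seeds of 2000 cells by four chase
times for the dilution fit; 100 competition runs of $N = 5000$ over 36
weeks plus 200 neutral controls; 1000 random p-value sets for BH
exactness.  `scripts/acceptance.R` recomputes the same quantities with 5
null and 10 biased recovery datasets and 10 dilution seeds — ensemble
sizes chosen as a deliberate compromise for a single-CPU run.

## Known limitations

* No spatial structure anywhere: clone fusion, boundary effects and
  contact-mediated competition are out of scope.
* The crowding feedback and the DFE are modelling hypotheses with
  config-exposed defaults, not fitted quantities.
* The likelihood uses basal clone sizes only; joint basal–suprabasal
  inference would require the full three-compartment state space.
* The LRT references ($\chi^2_1$ for fate bias, $\chi^2_2$ for rate
  heterogeneity) are boundary-approximate; AIC is the default decision
  rule.
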