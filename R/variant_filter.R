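#' Configuration of the somatic-variant post-filter
#'
#' Settings of the three post-caller filtering steps applied to ultra-deep
#' targeted sequencing calls from paired UV-exposed and unexposed biopsies:
#' removal of variants shared between both biopsies of a mouse,
#' Benjamini-Hochberg adjustment grouped per mouse with a q-value cutoff,
#' and a both-strands support requirement.
#'
#' @param q_max adjusted q-value threshold (default 0.1).
#' @param min_forward,min_reverse minimum supporting reads per strand.
#' @param biopsy_area_mm2 biopsy area used for burden (default 16 mm^2).
#' @param bh_group grouping unit of the BH families: `"mouse"` (both
#'   biopsies of a mouse pooled; the default reading of per-mouse
#'   correction) or `"biopsy"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(q_max = 0.1, min_forward = 1, min_reverse = 1,
                          biopsy_area_mm2 = 16,
                          bh_group = c("mouse", "biopsy")) {
  stopifnot(q_max > 0, q_max < 1, min_forward >= 0, min_reverse >= 0,
            biopsy_area_mm2 > 0)
  structure(list(q_max = q_max, min_forward = min_forward,
                 min_reverse = min_reverse,
                 biopsy_area_mm2 = biopsy_area_mm2,
                 bh_group = match.arg(bh_group)),
            class = "filter_config")
}

.variant_key <- function(records)
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")

#' Drop variants shared between paired biopsies of a mouse
#'
#' A somatic clone is not expected to span two distant biopsies, so a
#' variant detected in both the irradiated and the unexposed biopsy of the
#' same mouse is treated as a germline or shared artifact and every copy
#' is removed.  With more than two biopsies per mouse the rule
#' generalises: a variant present in at least two biopsies of the mouse
#' spanning both exposure labels is dropped.
#'
#' @param records a variant table (see [validate_variant_table()]).
#' @return The retained records.
#' @export
drop_paired_shared <- function(records) {
  records <- validate_variant_table(records)
  if (!nrow(records)) return(records)
  key <- paste(records$mouse_id, .variant_key(records), sep = "|")
  both <- tapply(records$exposure, key,
                 function(e) length(unique(e)) == 2)
  records[!both[key], , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up q-values with monotonicity enforcement:
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1.
#'
#' @param p vector of raw p-values in (0, 1].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Grouped Benjamini-Hochberg filter
#'
#' Applies [bh_adjust()] independently within each mouse (or biopsy, per
#' `config$bh_group`), annotates a `q_value` column, and keeps records
#' with `q_value < q_max`.
#'
#' @inheritParams drop_paired_shared
#' @param config a [filter_config()] object.
#' @return Retained records with a `q_value` column.
#' @export
bh_filter <- function(records, config = filter_config()) {
  records <- validate_variant_table(records)
  if (!nrow(records)) { records$q_value <- numeric(0); return(records) }
  grp <- if (config$bh_group == "mouse") records$mouse_id else records$biopsy_id
  q <- numeric(nrow(records))
  for (g in unique(grp)) {
    i <- grp == g
    q[i] <- bh_adjust(records$p_value[i])
  }
  records$q_value <- q
  records[q < config$q_max, , drop = FALSE]
}

#' Strand-support filter
#'
#' Keeps variants with at least `min_forward` supporting reads on the
#' forward strand and `min_reverse` on the reverse strand.
#'
#' @inheritParams bh_filter
#' @return Retained records.
#' @export
strand_filter <- function(records, config = filter_config()) {
  records <- validate_variant_table(records)
  if (!nrow(records)) return(records)
  if (any(is.na(records$fwd_reads)) || any(is.na(records$rev_reads)))
    stop("missing strand counts for record(s) ",
         paste(head(which(is.na(records$fwd_reads) |
                          is.na(records$rev_reads)), 5), collapse = ", "))
  keep <- records$fwd_reads >= config$min_forward &
    records$rev_reads >= config$min_reverse
  records[keep, , drop = FALSE]
}

#' Full variant post-filtering pipeline
#'
#' Applies, in order: [drop_paired_shared()], [bh_filter()],
#' [strand_filter()], and reports per-stage attrition.  The order matters:
#' shared variants are removed before the multiple-testing families are
#' formed, and the strand rule prunes the q-value survivors.
#'
#' @inheritParams bh_filter
#' @return List with `records` (survivors, with `q_value`) and
#'   `attrition` (data frame `stage, n_in, n_removed, n_out`).
#' @export
run_filter_pipeline <- function(records, config = filter_config()) {
  records <- validate_variant_table(records)
  s1 <- drop_paired_shared(records)
  s2 <- bh_filter(s1, config)
  s3 <- strand_filter(s2, config)
  attrition <- data.frame(
    stage = c("paired_shared", "bh_qvalue", "strand_support"),
    n_in = c(nrow(records), nrow(s1), nrow(s2)),
    n_removed = c(nrow(records) - nrow(s1), nrow(s1) - nrow(s2),
                  nrow(s2) - nrow(s3)),
    n_out = c(nrow(s1), nrow(s2), nrow(s3)))
  list(records = s3, attrition = attrition)
}

#' Mutation burden per biopsy
#'
#' Number of (filtered) variants per square millimetre of biopsy.
#' Biopsies with zero surviving variants report a burden of 0 when listed
#' in `all_biopsies`.
#'
#' @inheritParams bh_filter
#' @param all_biopsies optional data frame `biopsy_id, mouse_id, exposure`
#'   enumerating every sequenced biopsy (so empty biopsies appear).
#' @return Data frame `biopsy_id, mouse_id, exposure, n_variants,
#'   burden_per_mm2`.
#' @export
mutation_burden <- function(records, config = filter_config(),
                            all_biopsies = NULL) {
  records <- validate_variant_table(records)
  if (is.null(all_biopsies)) {
    all_biopsies <- unique(records[c("biopsy_id", "mouse_id", "exposure")])
  }
  n <- vapply(all_biopsies$biopsy_id,
              function(b) sum(records$biopsy_id == b), numeric(1))
  out <- all_biopsies
  out$n_variants <- as.numeric(n)
  out$burden_per_mm2 <- out$n_variants / config$biopsy_area_mm2
  rownames(out) <- NULL
  out
}

#' Mutational spectrum with pyrimidine strand collapse
#'
#' Counts single-nucleotide variants in the six pyrimidine-context
#' substitution classes (purine substitutions are complemented, e.g.
#' G>A counts as C>T) and reports the C>T fraction, the hallmark of the
#' UV-light mutational signature.  Non-SNV records are reported
#' separately, never silently dropped.
#'
#' @inheritParams bh_filter
#' @return List with `counts` (named vector over the six classes),
#'   `fractions`, `c_to_t_fraction` (`NA` with `undefined = TRUE` when no
#'   SNVs are present), `n_snv`, and `non_snv` (the excluded records).
#' @export
mutation_spectrum <- function(records) {
  records <- validate_variant_table(records)
  bases <- c("A", "C", "G", "T")
  is_snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    records$ref %in% bases & records$alt %in% bases
  snv <- records[is_snv, , drop = FALSE]
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  counts <- setNames(numeric(6), classes)
  if (nrow(snv)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- snv$ref; alt <- snv$alt
    pur <- ref %in% c("A", "G")
    ref[pur] <- comp[snv$ref[pur]]
    alt[pur] <- comp[snv$alt[pur]]
    tab <- table(factor(paste0(ref, ">", alt), levels = classes))
    counts[names(tab)] <- as.numeric(tab)
  }
  n_snv <- sum(counts)
  list(counts = counts,
       fractions = if (n_snv > 0) counts / n_snv else counts * NA,
       c_to_t_fraction = if (n_snv > 0) unname(counts["C>T"] / n_snv)
                         else NA_real_,
       undefined = n_snv == 0,
       n_snv = n_snv,
       non_snv = records[!is_snv, , drop = FALSE])
}
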