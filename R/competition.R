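#' Configuration of the clonal-competition simulator
#'
#' Non-spatial Moran model of clonal competition under ongoing mutagenesis:
#' a transgenic mutant clone is induced at frequency `f0` (default 1%) in a
#' wild-type progenitor population of constant size `n_cells`.  Division
#' events occur at total rate `lam * n_cells`; the divider is drawn with
#' probability proportional to `count * (1 + delta)` of its clone (fitness
#' interpreted as fate bias), and one uniformly random cell leaves the
#' basal layer, keeping the population constant.  Each division founds a
#' new clone with probability `mut_rate`; the new mutation's effect is
#' drawn from the distribution of fitness effects (DFE) and added to the
#' parental bias (clipped to \[-1, 1\], clips are counted).
#'
#' The default DFE is a point mass at zero with probability `p_neutral`
#' and an exponential positive tail with mean `s_mean` otherwise; a
#' deleterious exponential slice is available via `p_deleterious`.
#' An optional mutagen pulse (`n_preseed` clones of one cell each with DFE
#' fitness) models a single pre-treatment that loads the tissue with
#' standing mutations before the chase.
#'
#' @param n_cells constant progenitor population size.
#' @param f0 initial transgenic frequency (default 0.01).
#' @param lam division rate per week.
#' @param delta0 intrinsic fate bias of the transgenic mutation.
#' @param mut_rate new-mutation probability per division.
#' @param p_neutral DFE: probability of a neutral effect.
#' @param s_mean DFE: mean of the exponential beneficial tail.
#' @param p_deleterious DFE: probability of a deleterious effect.
#' @param s_del_mean DFE: mean magnitude of the deleterious exponential.
#' @param t_end simulated duration, weeks.
#' @param record_interval recording interval, weeks.
#' @param n_preseed standing mutant clones created at t = 0.
#' @return An object of class `competition_config`.
#' @export
competition_config <- function(n_cells = 5000, f0 = 0.01, lam = 1.2,
                               delta0 = 0.2, mut_rate = 2e-3,
                               p_neutral = 0.9, s_mean = 0.2,
                               p_deleterious = 0, s_del_mean = 0.1,
                               t_end = 36, record_interval = 1,
                               n_preseed = 50) {
  stopifnot(n_cells >= 2, f0 > 0, f0 < 1, lam > 0,
            mut_rate >= 0, mut_rate <= 1,
            p_neutral >= 0, p_deleterious >= 0,
            p_neutral + p_deleterious <= 1,
            s_mean > 0, s_del_mean > 0, t_end >= 0, record_interval > 0,
            n_preseed >= 0)
  if (n_cells * f0 < 1) stop("n_cells * f0 must be >= 1")
  structure(list(n_cells = as.integer(n_cells), f0 = f0, lam = lam,
                 delta0 = delta0, mut_rate = mut_rate,
                 p_neutral = p_neutral, s_mean = s_mean,
                 p_deleterious = p_deleterious, s_del_mean = s_del_mean,
                 t_end = t_end, record_interval = record_interval,
                 n_preseed = as.integer(n_preseed)),
            class = "competition_config")
}

#' Run one clonal-competition simulation
#'
#' @param config a [competition_config()] object.
#' @param seed integer seed; identical config and seed give identical
#'   output.
#' @return An object of class `competition_run`: list with `times`
#'   (weeks), `counts` (matrix, times x clones, rows summing to
#'   `n_cells`), `registry` (data frame `clone_id, parent_id, delta,
#'   is_transgenic_lineage, birth_time`), `n_clipped` and the `config`
#'   and `seed` used.
#' @examples
#' run <- run_competition(competition_config(n_cells = 500, t_end = 8), seed = 1)
#' head(transgenic_lineage_frequency(run))
#' @export
run_competition <- function(config, seed = NULL) {
  stopifnot(inherits(config, "competition_config"))
  if (!is.null(seed)) set.seed(seed)
  n0 <- as.integer(round(config$n_cells * config$f0))
  res <- moran_competition_cpp(config$n_cells, n0, config$lam, config$delta0,
                               config$mut_rate, config$p_neutral,
                               config$p_deleterious, config$s_mean,
                               config$s_del_mean, config$t_end,
                               config$record_interval, config$n_preseed)
  registry <- data.frame(clone_id = seq_along(res$delta),
                         parent_id = ifelse(res$parent < 0, NA_integer_,
                                            res$parent + 1L),
                         delta = res$delta,
                         is_transgenic_lineage = res$is_transgenic_lineage,
                         birth_time = res$birth_time)
  structure(list(times = res$times, counts = res$counts,
                 registry = registry, n_clipped = res$n_clipped,
                 config = config, seed = seed),
            class = "competition_run")
}

#' @exportS3Method base::print
print.competition_run <- function(x, ...) {
  cat(sprintf("competition_run: N = %d cells, %d clones, %d record times\n",
              x$config$n_cells, nrow(x$registry), length(x$times)))
  invisible(x)
}

#' Frequency of the transgenic lineage over time
#'
#' Sums the induced transgenic clone and all of its mutant descendants.
#'
#' @param run a [run_competition()] result.
#' @return Data frame `time_weeks, frequency`.
#' @export
transgenic_lineage_frequency <- function(run) {
  stopifnot(inherits(run, "competition_run"))
  reg <- run$registry
  if (any(!is.na(reg$parent_id) & !reg$parent_id %in% reg$clone_id))
    stop("registry inconsistency: orphan parent ids")
  sel <- reg$is_transgenic_lineage
  f <- rowSums(run$counts[, sel, drop = FALSE]) / run$config$n_cells
  data.frame(time_weeks = run$times, frequency = f)
}

#' Long-format clone frequencies for Muller-plot rendering
#'
#' @param run a [run_competition()] result.
#' @return Data frame `time_weeks, clone_id, parent_id, frequency`;
#'   frequencies at each time sum to 1 and parents precede children.
#' @export
muller_table <- function(run) {
  stopifnot(inherits(run, "competition_run"))
  reg <- run$registry
  n_t <- length(run$times)
  out <- data.frame(
    time_weeks = rep(run$times, times = nrow(reg)),
    clone_id = rep(reg$clone_id, each = n_t),
    parent_id = rep(reg$parent_id, each = n_t),
    frequency = as.vector(run$counts[, reg$clone_id]) / run$config$n_cells)
  out[order(out$time_weeks, out$clone_id), ]
}

#' Summarise an ensemble of competition runs
#'
#' For each run, reports the peak transgenic-lineage frequency, the time
#' of the peak, the final frequency, and whether the lineage rose then
#' fell: peak above `rise_factor * f0` and final frequency below
#' `fall_fraction` of the peak.
#'
#' @param runs list of [run_competition()] results.
#' @param rise_factor rise threshold relative to the induced frequency.
#' @param fall_fraction fall threshold relative to the peak.
#' @return Data frame, one row per run: `peak_frequency, peak_time,
#'   final_frequency, rose_then_fell`.
#' @export
summarize_runs <- function(runs, rise_factor = 2, fall_fraction = 0.5) {
  stopifnot(length(runs) >= 1)
  rows <- lapply(runs, function(run) {
    tf <- transgenic_lineage_frequency(run)
    i <- which.max(tf$frequency)
    peak <- tf$frequency[i]
    fin <- tf$frequency[nrow(tf)]
    data.frame(peak_frequency = peak, peak_time = tf$time_weeks[i],
               final_frequency = fin,
               rose_then_fell = peak > rise_factor * run$config$f0 &&
                 fin < fall_fraction * peak)
  })
  do.call(rbind, rows)
}

#' Simulate two-clone Moran fixation probabilities
#'
#' Runs the two-clone Moran process (one clone with fate-bias advantage
#' `s`, starting from `k0` cells) to absorption and returns the fraction
#' of replicates in which the advantaged clone fixed.  Used to check the
#' simulator against the exact absorbing-chain solution at small N.
#'
#' @param n_cells population size.
#' @param k0 initial size of the advantaged clone.
#' @param s fate-bias advantage (`delta`).
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return Fixation proportion (numeric scalar).
#' @export
moran_fixation_sim <- function(n_cells, k0, s, n_reps = 1000, seed = NULL) {
  stopifnot(n_cells >= 2, k0 >= 1, k0 < n_cells)
  if (!is.null(seed)) set.seed(seed)
  mean(moran_two_clone_fix_cpp(as.integer(n_cells), as.integer(k0), s,
                               as.integer(n_reps)))
}

#' Write the outputs of a competition run as delimited text
#'
#' Writes `<basename>_frequencies.tsv` (`time_weeks, clone_id, count`),
#' `<basename>_registry.tsv` and `<basename>_meta.txt` (config and seed).
#'
#' @param run a [run_competition()] result.
#' @param basename output path prefix.
#' @return The three paths, invisibly.
#' @export
write_competition_run <- function(run, basename) {
  stopifnot(inherits(run, "competition_run"))
  freq <- data.frame(time_weeks = rep(run$times, ncol(run$counts)),
                     clone_id = rep(seq_len(ncol(run$counts)),
                                    each = length(run$times)),
                     count = as.vector(run$counts))
  freq <- freq[freq$count > 0 | freq$time_weeks == 0, ]
  p1 <- paste0(basename, "_frequencies.tsv")
  p2 <- paste0(basename, "_registry.tsv")
  p3 <- paste0(basename, "_meta.txt")
  write.table(freq, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$registry, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(unclass(run$config), list(seed = if (is.null(run$seed)) NA else run$seed))
  write_kv(meta, p3)
  invisible(c(p1, p2, p3))
}
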