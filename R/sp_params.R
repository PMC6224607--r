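#' Parameters of the single-progenitor fate model
#'
#' The interfollicular epidermis is maintained by a single population of
#' progenitor cells whose divisions have stochastic outcome: two progenitors
#' (PP), two differentiating basal daughters (DD), or one of each (PD).
#' In the balanced (homeostatic) model the PP and DD probabilities are equal
#' to `r`.  A fate imbalance `delta` tilts the symmetric outcomes,
#' \eqn{p_{PP} = r + \Delta/2}, \eqn{p_{DD} = r - \Delta/2},
#' \eqn{p_{PD} = 1 - 2r}, so that `delta = 0` recovers the balanced model
#' exactly and `delta` alone measures the excess of duplicating over
#' differentiating divisions.  Differentiated basal cells stratify into the
#' suprabasal layer at rate `gamma` and suprabasal cells are shed at rate
#' `mu`.  All rates are per week.
#'
#' @param r probability of a symmetric division outcome in the balanced
#'   model, in (0, 0.5].
#' @param lam progenitor division rate (divisions per progenitor per week).
#' @param delta fate imbalance \eqn{\Delta = p_{PP} - p_{DD}}, must keep all
#'   fate probabilities in \[0, 1\] (i.e. `delta` in \[-2r, 2r\] and
#'   \[2r - 1, 1 - 2r\] jointly).
#' @param gamma stratification rate of differentiated basal cells, per week.
#' @param mu shedding rate of suprabasal cells, per week.
#'
#' @return An object of class `sp_params`.
#' @examples
#' p <- sp_params(r = 0.25, lam = 1.2, delta = 0)
#' fate_probs(p)
#' @export
sp_params <- function(r = 0.25, lam = 1.2, delta = 0, gamma = 3, mu = 1) {
  stopifnot(is.numeric(r), is.numeric(lam), is.numeric(delta),
            is.numeric(gamma), is.numeric(mu))
  if (r <= 0 || r > 0.5) stop("'r' must lie in (0, 0.5]")
  if (lam < 0) stop("'lam' must be >= 0")
  if (gamma < 0) stop("'gamma' must be >= 0")
  if (mu < 0) stop("'mu' must be >= 0")
  p <- structure(list(r = r, lam = lam, delta = delta,
                      gamma = gamma, mu = mu),
                 class = "sp_params")
  fp <- fate_probs(p)   # errors if delta pushes probabilities outside [0,1]
  stopifnot(abs(sum(fp) - 1) < 1e-12)
  p
}

#' Division fate probabilities implied by a parameter set
#'
#' @param params an [sp_params()] object.
#' @return Named vector `c(pp, pd, dd)` summing to 1.
#' @export
fate_probs <- function(params) {
  pp <- params$r + params$delta / 2
  dd <- params$r - params$delta / 2
  pd <- 1 - 2 * params$r
  if (min(pp, pd, dd) < -1e-12 || max(pp, pd, dd) > 1 + 1e-12)
    stop("fate probabilities outside [0,1]: p_PP=", signif(pp, 4),
         " p_PD=", signif(pd, 4), " p_DD=", signif(dd, 4))
  c(pp = max(pp, 0), pd = max(pd, 0), dd = max(dd, 0))
}

#' @exportS3Method base::print
print.sp_params <- function(x, ...) {
  fp <- fate_probs(x)
  cat("Single-progenitor parameters\n")
  cat(sprintf("  r = %.4g  lam = %.4g /wk  delta = %.4g  gamma = %.4g /wk  mu = %.4g /wk\n",
              x$r, x$lam, x$delta, x$gamma, x$mu))
  cat(sprintf("  fate probabilities: PP %.4g  PD %.4g  DD %.4g\n",
              fp["pp"], fp["pd"], fp["dd"]))
  invisible(x)
}

#' Read / write single-progenitor parameters as a flat key-value file
#'
#' The config uses one `key = value` pair per line with keys exactly
#' `r, lam, delta, gamma, mu`; lines starting with `#` are comments.
#'
#' @param params an [sp_params()] object.
#' @param path file path.
#' @return `read_sp_params()` returns an [sp_params()] object;
#'   `write_sp_params()` returns `path` invisibly.
#' @export
write_sp_params <- function(params, path) {
  stopifnot(inherits(params, "sp_params"))
  write_kv(params[c("r", "lam", "delta", "gamma", "mu")], path)
}

#' @rdname write_sp_params
#' @export
read_sp_params <- function(path) {
  kv <- read_kv(path)
  need <- c("r", "lam", "delta", "gamma", "mu")
  if (!all(need %in% names(kv)))
    stop("missing keys: ", paste(setdiff(need, names(kv)), collapse = ", "))
  sp_params(r = as.numeric(kv$r), lam = as.numeric(kv$lam),
            delta = as.numeric(kv$delta), gamma = as.numeric(kv$gamma),
            mu = as.numeric(kv$mu))
}

#' Convert between weeks and days for rate or time values
#'
#' Explicit unit helpers; the package works in weeks throughout.
#' @param x numeric vector of times (or rates, for the `rate_` versions).
#' @return converted numeric vector.
#' @export
weeks_to_days <- function(x) x * 7

#' @rdname weeks_to_days
#' @export
days_to_weeks <- function(x) x / 7

#' @rdname weeks_to_days
#' @export
rate_per_week_to_per_day <- function(x) x / 7

#' @rdname weeks_to_days
#' @export
rate_per_day_to_per_week <- function(x) x * 7
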