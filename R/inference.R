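#' Specification of a single-progenitor fit
#'
#' Declares which parameters are free, the fixed values of the rest, the
#' clone detection rule and the optimiser settings used by
#' [fit_sp_params()].  The likelihood conditions on detection: wholemount
#' scoring only records clones with at least `detection_min` basal cells,
#' so extinct clones are unobserved.
#'
#' @param free character vector of free parameters, subset of
#'   `c("r", "lam", "delta", "gamma")`; at least one.
#' @param fixed named list of values for the non-free parameters (defaults
#'   from [sp_params()] are used for anything not given).
#' @param detection_min minimum observable basal clone size.
#' @param bounds named list of `c(lower, upper)` optimiser bounds.
#' @param n_boot bootstrap replicates (clone resampling).
#' @param n_start random restarts for multi-parameter fits.
#' @param n_grid grid points of the single-parameter likelihood profile.
#' @param n_max master-equation truncation; observed sizes beyond it enter
#'   the likelihood as a censored "size > n_max" category with the
#'   reported boundary mass.
#' @param pmf_tol uniformization tolerance passed to [clone_size_pmf()].
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free = "delta",
                     fixed = list(),
                     detection_min = 1,
                     bounds = list(r = c(0.05, 0.5), lam = c(0.1, 6),
                                   delta = c(-0.2, 0.5), gamma = c(0.2, 10)),
                     n_boot = 200, n_start = 5, n_max = 100,
                     n_grid = 41, pmf_tol = 1e-10) {
  valid <- c("r", "lam", "delta", "gamma")
  stopifnot(length(free) >= 1, all(free %in% valid), detection_min >= 1,
            n_grid >= 11)
  defaults <- unclass(sp_params())
  fixed_full <- utils::modifyList(defaults[c(valid, "mu")], fixed)
  structure(list(free = free, fixed = fixed_full,
                 detection_min = detection_min, bounds = bounds,
                 n_boot = n_boot, n_start = n_start, n_max = n_max,
                 n_grid = n_grid, pmf_tol = pmf_tol),
            class = "fit_spec")
}

.spec_params <- function(spec, x) {
  v <- spec$fixed
  v[spec$free] <- as.list(x)
  sp_params(r = v$r, lam = v$lam, delta = v$delta, gamma = v$gamma, mu = v$mu)
}

# per-time log conditional basal-size pmf: entries 1..n_max are sizes,
# entry n_max + 1 is the censored "> n_max" category
.basal_logpmf_table <- function(params, times, spec) {
  pmf <- suppressWarnings(
    clone_size_pmf(params, times, n_max = spec$n_max, tol = spec$pmf_tol))
  lapply(seq_along(times), function(k) {
    bs <- basal_size_pmf(pmf, k)
    bmass <- attr(bs, "boundary_mass")
    keep <- bs$size >= spec$detection_min
    surv <- sum(bs$prob[keep]) + bmass
    lp <- rep(-Inf, spec$n_max)   # index s = basal size s; slot n_max + 1
    lp[bs$size[keep]] <- log(pmax(bs$prob[keep], 1e-300) / surv)
    c(lp, log(max(bmass, 1e-300) / surv))   # censored "> n_max" category
  })
}

# per-clone log-probabilities given a table from .basal_logpmf_table()
.clone_logp <- function(tabs, times, clones, spec) {
  ti <- match(clones$time_weeks, times)
  size <- pmin(clones$n_basal, spec$n_max + 1)
  vapply(seq_len(nrow(clones)),
         function(i) tabs[[ti[i]]][size[i]], numeric(1))
}

#' Log-likelihood of a clone table under the single-progenitor model
#'
#' Sum over clones of the log probability of the observed basal size at
#' the observation time, conditioned on the clone being detected
#' (basal size >= `detection_min`), with the size distribution from the
#' master equation.  Sizes beyond the truncation contribute the censored
#' boundary category.
#'
#' @param params an [sp_params()] object.
#' @param clones clone table (see [read_clone_table()] for the contract).
#' @param spec a [fit_spec()] object.
#' @return Log-likelihood (scalar).
#' @export
clone_loglik <- function(params, clones, spec = fit_spec()) {
  clones <- validate_clone_table(clones)
  if (!nrow(clones)) stop("empty clone table")
  if (any(clones$n_basal < spec$detection_min))
    stop("clone table contains sizes below the detection rule")
  times <- sort(unique(clones$time_weeks))
  tabs <- .basal_logpmf_table(params, times, spec)
  lp <- .clone_logp(tabs, times, clones, spec)
  if (any(!is.finite(lp)))
    stop("non-finite log-likelihood for clone(s) ",
         paste(head(which(!is.finite(lp)), 5), collapse = ", "))
  sum(lp)
}

#' Maximum-likelihood fit of single-progenitor parameters
#'
#' Bounded maximisation of [clone_loglik()] over the free parameters of
#' `spec`.  Single-parameter fits use golden-section search; fits with
#' several free parameters use multi-start L-BFGS-B.  Confidence intervals
#' come from bootstrap resampling of clones; for a single free parameter
#' the bootstrap reuses a profile of per-clone log-probabilities on a
#' parameter grid (with local quadratic refinement), making replicates
#' cheap.
#'
#' @inheritParams clone_loglik
#' @param seed optional seed for multi-start draws and the bootstrap.
#' @param conf confidence level of the bootstrap interval.
#' @return An object of class `sp_fit`: list with `estimate` (named),
#'   `loglik`, `ci` (matrix, one row per free parameter), `n_boot`,
#'   `convergence` and the `spec` used.
#' @export
fit_sp_params <- function(clones, spec = fit_spec(), seed = NULL,
                          conf = 0.95) {
  clones <- validate_clone_table(clones)
  if (!nrow(clones)) stop("empty clone table")
  if (length(unique(clones$time_weeks)) < 2)
    warning("fewer than 2 timepoints: parameters may be unidentifiable")
  if (!is.null(seed)) set.seed(seed)
  times <- sort(unique(clones$time_weeks))
  loglik_at <- function(x) {
    tabs <- .basal_logpmf_table(.spec_params(spec, x), times, spec)
    lp <- .clone_logp(tabs, times, clones, spec)
    if (any(!is.finite(lp))) -1e10 else sum(lp)
  }
  # quadratic refinement of a grid maximum (offset clamped to one step)
  refine <- function(grid, y) {
    j <- which.max(y)
    if (j == 1 || j == length(grid)) return(c(grid[j], y[j]))
    h <- grid[2] - grid[1]
    denom <- y[j - 1] - 2 * y[j] + y[j + 1]
    off <- if (denom < 0) 0.5 * (y[j - 1] - y[j + 1]) / denom else 0
    off <- max(min(off, 1), -1)
    c(grid[j] + off * h, y[j] - 0.25 * (y[j - 1] - y[j + 1]) * off)
  }

  k <- length(spec$free)
  ci <- NULL
  if (k == 1) {
    # single free parameter: evaluate per-clone log-probabilities on a
    # profile grid once; the point estimate and every bootstrap replicate
    # reuse it (resampling only reweights clones)
    b <- spec$bounds[[spec$free]]
    grid <- seq(b[1], b[2], length.out = spec$n_grid)
    M <- vapply(grid, function(g) {
      tabs <- .basal_logpmf_table(.spec_params(spec, g), times, spec)
      .clone_logp(tabs, times, clones, spec)
    }, numeric(nrow(clones)))           # clones x grid
    M[!is.finite(M)] <- -1e10
    pt <- refine(grid, colSums(M))
    est <- setNames(pt[1], spec$free)
    ll <- loglik_at(pt[1])
    conv <- 0L
    if (spec$n_boot > 0) {
      boot_est <- replicate(spec$n_boot, {
        w <- tabulate(sample.int(nrow(clones), replace = TRUE),
                      nbins = nrow(clones))
        refine(grid, as.numeric(w %*% M))[1]
      })
      a <- (1 - conf) / 2
      ci <- matrix(quantile(boot_est, c(a, 1 - a), names = FALSE), nrow = 1,
                   dimnames = list(spec$free, c("lower", "upper")))
    }
  } else {
    lo <- vapply(spec$free, function(p) spec$bounds[[p]][1], numeric(1))
    hi <- vapply(spec$free, function(p) spec$bounds[[p]][2], numeric(1))
    best <- NULL
    for (s in seq_len(spec$n_start)) {
      x0 <- lo + runif(k) * (hi - lo)
      o <- tryCatch(optim(x0, function(x) -loglik_at(x), method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(factr = 1e9)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("no optimiser start converged")
    est <- setNames(best$par, spec$free)
    ll <- -best$value
    conv <- best$convergence
    if (spec$n_boot > 0) {
      boot_est <- replicate(spec$n_boot, {
        idx <- sample.int(nrow(clones), replace = TRUE)
        bs <- spec; bs$n_boot <- 0
        fit_sp_params(clones[idx, ], bs)$estimate
      })
      boot_est <- matrix(boot_est, nrow = k)
      a <- (1 - conf) / 2
      ci <- t(apply(boot_est, 1, quantile, probs = c(a, 1 - a),
                    names = FALSE))
      dimnames(ci) <- list(spec$free, c("lower", "upper"))
    }
  }
  structure(list(estimate = est, loglik = ll, ci = ci, conf = conf,
                 n_boot = spec$n_boot, convergence = conv, spec = spec,
                 n_clones = nrow(clones)),
            class = "sp_fit")
}

#' @exportS3Method base::print
print.sp_fit <- function(x, ...) {
  cat("Single-progenitor fit (", x$n_clones, " clones)\n", sep = "")
  for (p in names(x$estimate)) {
    line <- sprintf("  %s = %.4f", p, x$estimate[[p]])
    if (!is.null(x$ci))
      line <- sprintf("%s  (%.0f%% CI %.4f to %.4f)", line, 100 * x$conf,
                      x$ci[p, 1], x$ci[p, 2])
    cat(line, "\n")
  }
  cat(sprintf("  loglik = %.3f\n", x$loglik))
  invisible(x)
}

#' Compare balanced and fate-biased models on a clone table
#'
#' Fits the model with `delta` fixed at 0 (balanced fate) and with
#' `delta` free (biased fate), and reports the likelihood-ratio statistic
#' and the AIC difference.  The chi-squared reference for the LRT is
#' approximate when the estimate sits on a bound.
#'
#' @inheritParams clone_loglik
#' @param spec a [fit_spec()]; `"delta"` must be among its free
#'   parameters (it is removed for the balanced fit).
#' @param seed optional seed passed to both fits.
#' @return List with `loglik_null`, `loglik_alt`, `lr`, `p_value`
#'   (df = 1), `aic_null`, `aic_alt`, `delta_aic`
#'   (`aic_null - aic_alt`, positive favours the biased model),
#'   `preferred`, and the biased-fit estimates.
#' @export
compare_models <- function(clones, spec = fit_spec(n_boot = 0),
                           seed = NULL) {
  if (!"delta" %in% spec$free)
    stop("'delta' must be a free parameter for model comparison")
  alt <- fit_sp_params(clones, spec, seed = seed)
  null_free <- setdiff(spec$free, "delta")
  if (length(null_free)) {
    ns <- spec; ns$free <- null_free; ns$fixed$delta <- 0; ns$n_boot <- 0
    null_fit <- fit_sp_params(clones, ns, seed = seed)
    ll0 <- null_fit$loglik
  } else {
    ns <- spec; ns$fixed$delta <- 0; ns$free <- character(0)
    ll0 <- clone_loglik(.spec_params(ns, numeric(0)), clones, ns)
    null_fit <- NULL
  }
  k1 <- length(spec$free); k0 <- k1 - 1
  lr <- max(0, 2 * (alt$loglik - ll0))
  aic0 <- 2 * k0 - 2 * ll0
  aic1 <- 2 * k1 - 2 * alt$loglik
  list(loglik_null = ll0, loglik_alt = alt$loglik, lr = lr,
       p_value = pchisq(lr, df = 1, lower.tail = FALSE),
       aic_null = aic0, aic_alt = aic1, delta_aic = aic0 - aic1,
       preferred = if (aic1 < aic0) "biased" else "balanced",
       fit_alt = alt, fit_null = null_fit)
}

#' Serialise a fit result as key-value text with provenance
#'
#' @param fit an [fit_sp_params()] result.
#' @param path output file.
#' @param input_hash optional hash (e.g. `tools::md5sum()`) of the input
#'   clone table file.
#' @param seed the seed used for the fit, if any.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, input_hash = NA, seed = NA) {
  stopifnot(inherits(fit, "sp_fit"))
  kv <- list()
  for (p in names(fit$estimate)) kv[[paste0("estimate_", p)]] <- fit$estimate[[p]]
  if (!is.null(fit$ci))
    for (p in rownames(fit$ci)) {
      kv[[paste0("ci_lower_", p)]] <- fit$ci[p, 1]
      kv[[paste0("ci_upper_", p)]] <- fit$ci[p, 2]
    }
  kv$loglik <- fit$loglik
  kv$n_clones <- fit$n_clones
  kv$n_boot <- fit$n_boot
  kv$free <- paste(fit$spec$free, collapse = ",")
  kv$detection_min <- fit$spec$detection_min
  kv$n_max <- fit$spec$n_max
  kv$input_hash <- input_hash
  kv$seed <- seed
  write_kv(kv, path)
}
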