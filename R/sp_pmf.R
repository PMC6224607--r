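#' Clone-size probability mass function from the master equation
#'
#' Solves the truncated master equation of the single-progenitor process
#' forward from an initial state, returning the joint pmf over
#' `(n_p, n_d)` at each requested time.  The solver uses uniformization
#' (randomization) of the truncated chain, which is exact up to the Poisson
#' tail bound `tol`; probability that leaves the truncation accumulates in
#' a lumped boundary state and is reported per time so callers can enlarge
#' `n_max`.
#'
#' @param params an [sp_params()] object.
#' @param t numeric vector of times (weeks), all >= 0.
#' @param n_max truncation bound on basal clone size.
#' @param init initial state, numeric `c(n_p, n_d)` (a starting suprabasal
#'   count is irrelevant to the basal pmf and not tracked here).
#' @param tol truncation tolerance of the uniformization series.
#' @param boundary_tol boundary mass above this triggers a warning (also
#'   recorded in the result as `boundary_warning`).
#' @return An object of class `clone_pmf`: list with `times`, `P`
#'   (matrix states x times), `space`, `boundary_mass`, `params`, `init`.
#' @examples
#' pmf <- clone_size_pmf(sp_params(), t = c(1.5, 3), n_max = 40)
#' colSums(pmf$P)  # mass conservation
#' @export
clone_size_pmf <- function(params, t, n_max = 100, init = c(1, 0),
                           tol = 1e-10, boundary_tol = 1e-4) {
  stopifnot(all(t >= 0), length(init) >= 2)
  gen <- sp_generator(params, n_max)
  space <- gen$space
  if (init[1] + init[2] > n_max) stop("initial state outside truncation")
  i0 <- space$index(init[1], init[2])
  p0 <- numeric(space$n_states); p0[i0] <- 1

  Lambda <- max(-Matrix::diag(gen$Q))
  P <- if (Lambda > 0) {
    Pt <- Matrix::t(Matrix::Diagonal(space$n_states) + gen$Q / Lambda)
    Pt <- methods::as(methods::as(Pt, "CsparseMatrix"), "generalMatrix")
    ctmc_uniformize_cpp(Pt@p, Pt@i, Pt@x, space$n_states, Lambda,
                        as.numeric(t), p0, tol)
  } else {
    matrix(p0, nrow = space$n_states, ncol = length(t))
  }
  boundary_mass <- P[space$i_boundary, ]
  res <- structure(list(times = as.numeric(t), P = P, space = space,
                        boundary_mass = boundary_mass, params = params,
                        init = init,
                        boundary_warning = any(boundary_mass > boundary_tol)),
                   class = "clone_pmf")
  if (res$boundary_warning)
    warning(sprintf("boundary mass up to %.3g exceeds %.3g; increase n_max",
                    max(boundary_mass), boundary_tol))
  res
}

#' @exportS3Method base::print
print.clone_pmf <- function(x, ...) {
  cat(sprintf("clone_pmf: n_max = %d (%d states), %d time(s)\n",
              x$space$n_max, x$space$n_states, length(x$times)))
  cat("  boundary mass:", signif(x$boundary_mass, 3), "\n")
  invisible(x)
}

#' Marginal basal clone-size distribution
#'
#' Collapses the joint `(n_p, n_d)` pmf to the distribution of basal clone
#' size `n_p + n_d` (the quantity scored in wholemount imaging).
#'
#' @param pmf a [clone_size_pmf()] result.
#' @param which index of the requested time (default: last).
#' @return Data frame with `size` (0..n_max) and `prob`; the lumped
#'   boundary mass (size > n_max) is attached as attribute
#'   `"boundary_mass"`.
#' @export
basal_size_pmf <- function(pmf, which = length(pmf$times)) {
  stopifnot(inherits(pmf, "clone_pmf"))
  st <- pmf$space$states
  sizes <- st$n_p + st$n_d
  p <- pmf$P[seq_len(nrow(st)), which]
  prob <- vapply(0:pmf$space$n_max, function(s) sum(p[sizes == s]), numeric(1))
  structure(data.frame(size = 0:pmf$space$n_max, prob = prob),
            boundary_mass = pmf$boundary_mass[which])
}

#' Probability that a clone has been lost from the basal layer
#'
#' Probability that a clone started from `init` has no basal cells left
#' (`n_p = n_d = 0`) at time `t`: the fate of the majority of neutral
#' clones, which are lost by differentiation and shedding.
#'
#' @inheritParams clone_size_pmf
#' @return Numeric vector of extinction probabilities, one per time.
#' @export
extinction_probability <- function(params, t, n_max = 60, init = c(1, 0),
                                   tol = 1e-10, boundary_tol = 1e-4) {
  pmf <- clone_size_pmf(params, t, n_max = n_max, init = init, tol = tol,
                        boundary_tol = boundary_tol)
  as.numeric(pmf$P[pmf$space$i_extinct, ])
}

#' Expected clone composition over time (closed form)
#'
#' The first moments obey a closed linear system:
#' \deqn{dE[n_p]/dt = \lambda\Delta E[n_p]}
#' \deqn{dE[n_d]/dt = \lambda(1-\Delta) E[n_p] - \Gamma E[n_d]}
#' \deqn{dE[n_s]/dt = \Gamma E[n_d] - \mu E[n_s]}
#' solved exactly by the matrix exponential; in particular
#' \eqn{E[n_p](t) = n_p(0) e^{\lambda\Delta t}} so a balanced clone
#' (`delta = 0`) has martingale progenitor number.
#'
#' @param params an [sp_params()] object.
#' @param t numeric vector of times (weeks).
#' @param init initial counts `c(n_p, n_d, n_s)`.
#' @return Matrix `length(t) x 3` with columns `n_p`, `n_d`, `n_s`.
#' @export
mean_counts <- function(params, t, init = c(1, 0, 0)) {
  stopifnot(length(init) == 3)
  A <- rbind(c(params$lam * params$delta, 0, 0),
             c(params$lam * (1 - params$delta), -params$gamma, 0),
             c(0, params$gamma, -params$mu))
  out <- t(vapply(as.numeric(t), function(tt)
    as.numeric(Matrix::expm(A * tt) %*% init), numeric(3)))
  colnames(out) <- c("n_p", "n_d", "n_s")
  out
}

#' Size statistics of surviving clones
#'
#' Mean and quantiles of basal clone size conditioned on the clone still
#' being detectable (basal size >= `detection_min`), the quantity plotted
#' in clone-size distributions.
#'
#' @inheritParams clone_size_pmf
#' @param detection_min minimum observable basal size (default 1).
#' @param probs quantile levels.
#' @return Data frame with one row per time: `t`, `p_surviving`,
#'   `mean_basal` and requested quantiles.
#' @export
surviving_clone_size_stats <- function(params, t, n_max = 100,
                                       init = c(1, 0), detection_min = 1,
                                       probs = c(0.25, 0.5, 0.75),
                                       tol = 1e-10, boundary_tol = 1e-4) {
  pmf <- clone_size_pmf(params, t, n_max = n_max, init = init, tol = tol,
                        boundary_tol = boundary_tol)
  rows <- lapply(seq_along(pmf$times), function(k) {
    bs <- basal_size_pmf(pmf, k)
    bmass <- attr(bs, "boundary_mass")
    keep <- bs$size >= detection_min
    surv <- sum(bs$prob[keep]) + bmass
    if (surv < 1e-6)
      stop("survival probability below 1e-6 at t = ", pmf$times[k],
           "; conditioning is degenerate")
    # boundary states counted at size n_max + 1 (a lower bound on their size)
    m <- (sum(bs$size[keep] * bs$prob[keep]) + bmass * (n_max + 1)) / surv
    cdf <- cumsum(bs$prob[keep]) / surv
    qs <- vapply(probs, function(q) bs$size[keep][match(TRUE, cdf >= q)],
                 numeric(1))
    c(t = pmf$times[k], p_surviving = surv, mean_basal = m,
      setNames(qs, paste0("q", probs * 100)))
  })
  as.data.frame(do.call(rbind, rows))
}
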