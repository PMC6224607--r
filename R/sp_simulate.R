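#' Exact stochastic simulation of a single clone
#'
#' Gillespie simulation of the single-progenitor process, tracking
#' progenitor, differentiated basal and suprabasal counts through every
#' event.  A clone is basal-extinct once `n_p = n_d = 0`; remaining
#' suprabasal cells continue to shed.
#'
#' @param params an [sp_params()] object.
#' @param t_end end time (weeks), >= 0.
#' @param init initial counts `c(n_p, n_d, n_s)`.
#' @param seed integer seed; the path is reproducible given the seed.
#' @return Data frame with columns `t`, `n_p`, `n_d`, `n_s`, one row per
#'   event plus a closing row at `t_end`.
#' @examples
#' path <- simulate_clone(sp_params(), t_end = 4, seed = 1)
#' tail(path, 3)
#' @export
simulate_clone <- function(params, t_end, init = c(1, 0, 0), seed = NULL) {
  stopifnot(inherits(params, "sp_params"), t_end >= 0, length(init) == 3,
            all(init >= 0))
  if (!is.null(seed)) set.seed(seed)
  fp <- fate_probs(params)
  m <- sp_gillespie_path_cpp(params$lam, fp[["pp"]], fp[["dd"]],
                             params$gamma, params$mu,
                             as.integer(init[1]), as.integer(init[2]),
                             as.integer(init[3]), t_end)
  as.data.frame(m)
}

#' Simulate many clones, keeping only the final state
#'
#' Batch Gillespie simulation used for Monte-Carlo cross-checks of the
#' master-equation solution and by the synthetic-data generator.
#'
#' @inheritParams simulate_clone
#' @param n number of independent clones.
#' @return Data frame with `n` rows and columns `n_p`, `n_d`, `n_s`: the
#'   state of each clone at `t_end`.
#' @export
simulate_clone_final <- function(params, t_end, n, init = c(1, 0, 0),
                                 seed = NULL) {
  stopifnot(inherits(params, "sp_params"), t_end >= 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  fp <- fate_probs(params)
  m <- sp_gillespie_final_cpp(params$lam, fp[["pp"]], fp[["dd"]],
                              params$gamma, params$mu,
                              as.integer(init[1]), as.integer(init[2]),
                              as.integer(init[3]), t_end, as.integer(n))
  as.data.frame(m)
}
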