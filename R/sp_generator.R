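#' Enumerate the truncated clone state space
#'
#' Clone states are pairs `(n_p, n_d)` of progenitor and differentiated
#' basal cell counts with `n_p + n_d <= n_max`, ordered by total basal size
#' then by `n_p`.  One extra lumped "boundary" state collects all mass that
#' leaves the truncation, so truncation error is observable rather than
#' silently dropped.  Suprabasal counts are marginalised out here (they do
#' not influence basal dynamics); the Gillespie path tracks them fully.
#'
#' @param n_max truncation bound on basal clone size (`n_p + n_d`), >= 2.
#' @return List with `states` (data frame `n_p`, `n_d`), `n_states`
#'   (including the boundary), `i_extinct`, `i_boundary`, and `index()`,
#'   a vectorised map from `(n_p, n_d)` to state index.
#' @export
sp_state_space <- function(n_max) {
  stopifnot(n_max >= 2)
  s <- rep.int(0:n_max, 0:n_max + 1L)
  np <- unlist(lapply(0:n_max, function(k) 0:k), use.names = FALSE)
  states <- data.frame(n_p = np, n_d = s - np)
  n_int <- nrow(states)
  index <- function(n_p, n_d) {
    tot <- n_p + n_d
    ifelse(tot > n_max, n_int + 1L, (tot * (tot + 1L)) %/% 2L + n_p + 1L)
  }
  list(states = states, n_states = n_int + 1L,
       i_extinct = 1L, i_boundary = n_int + 1L,
       n_max = n_max, index = index)
}

#' Transition-rate generator of the single-progenitor clone process
#'
#' Builds the sparse infinitesimal generator `Q` (rows = source states) of
#' the basal-clone continuous-time Markov chain: divisions at rate
#' `lam * n_p` with outcomes PP (`n_p + 1`), DD (`n_p - 1`, `n_d + 2`) and
#' PD (`n_d + 1`), and stratification at rate `gamma * n_d`
#' (`n_d - 1`).  Transitions that would exceed the truncation feed the
#' absorbing boundary state.
#'
#' @param params an [sp_params()] object.
#' @param n_max truncation bound, >= 2.
#' @return List with `Q` (a `dgCMatrix`), the state `space`, and `params`.
#' @export
sp_generator <- function(params, n_max) {
  stopifnot(inherits(params, "sp_params"))
  fp <- fate_probs(params)
  space <- sp_state_space(n_max)
  st <- space$states
  n <- space$n_states
  idx <- space$index

  from <- integer(0); to <- integer(0); rate <- numeric(0)
  add <- function(i, j, r) {
    keep <- r > 0
    from <<- c(from, i[keep]); to <<- c(to, j[keep]); rate <<- c(rate, r[keep])
  }
  i_all <- seq_len(nrow(st))
  div <- st$n_p > 0
  if (any(div) && params$lam > 0) {
    i <- i_all[div]; np <- st$n_p[div]; nd <- st$n_d[div]
    base <- params$lam * np
    add(i, idx(np + 1L, nd),      base * fp[["pp"]])
    add(i, idx(np - 1L, nd + 2L), base * fp[["dd"]])
    add(i, idx(np, nd + 1L),      base * fp[["pd"]])
  }
  strat <- st$n_d > 0
  if (any(strat) && params$gamma > 0) {
    i <- i_all[strat]
    add(i, idx(st$n_p[strat], st$n_d[strat] - 1L), params$gamma * st$n_d[strat])
  }
  out_rate <- numeric(n)
  tot <- tapply(rate, from, sum)
  out_rate[as.integer(names(tot))] <- tot
  Q <- Matrix::sparseMatrix(i = c(from, seq_len(n)), j = c(to, seq_len(n)),
                            x = c(rate, -out_rate), dims = c(n, n))
  list(Q = Q, space = space, params = params)
}
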