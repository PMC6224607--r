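# Independent oracles used across the suite.  These are deliberately
# naive implementations (closed forms, brute-force enumeration, linear
# solves) kept separate from the code paths they check.

# critical birth-death process with birth = death = b per individual,
# started from one individual
bd_extinction_critical <- function(b, t) b * t / (1 + b * t)
bd_surviving_mean_critical <- function(b, t) 1 + b * t

# extinction probability of the progenitor branching process as t -> inf:
# smallest root of the offspring generating function fixed point
branching_extinction_limit <- function(r, delta) {
  p_pp <- r + delta / 2
  p_dd <- r - delta / 2
  if (p_pp <= p_dd) return(1)
  min(1, p_dd / p_pp)
}

# textbook Benjamini-Hochberg step-up written as an explicit loop
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# exact fixation probability of the selected clone (advantage s, initial
# size k0) in the Moran scheme used by the simulator: divider chosen
# proportional to count * (1 + delta), uniform removal among the
# pre-division population.  Brute-force linear solve on the k = 0..N chain.
moran_fixation_exact <- function(N, k0, s) {
  ks <- 1:(N - 1)
  W <- ks * (1 + s) + (N - ks)
  up <- (ks * (1 + s) / W) * ((N - ks) / N)
  down <- ((N - ks) / W) * (ks / N)
  # u_k = up_k u_{k+1} + down_k u_{k-1} + (1 - up - down) u_k
  A <- matrix(0, N - 1, N - 1)
  b <- numeric(N - 1)
  for (k in ks) {
    A[k, k] <- up[k] + down[k]
    if (k < N - 1) A[k, k + 1] <- -up[k]
    if (k > 1) A[k, k - 1] <- -down[k]
    if (k == N - 1) b[k] <- up[k]   # u_N = 1
  }
  u <- solve(A, b)
  if (k0 == 0) 0 else if (k0 == N) 1 else u[k0]
}

# brute-force enumeration of the single-progenitor transition rates out of
# one state, straight from the event stoichiometry
sp_rates_by_hand <- function(params, n_p, n_d) {
  fp <- fate_probs(params)
  out <- list()
  if (n_p > 0) {
    out[[length(out) + 1]] <- list(to = c(n_p + 1, n_d),
                                   rate = params$lam * n_p * fp[["pp"]])
    out[[length(out) + 1]] <- list(to = c(n_p - 1, n_d + 2),
                                   rate = params$lam * n_p * fp[["dd"]])
    out[[length(out) + 1]] <- list(to = c(n_p, n_d + 1),
                                   rate = params$lam * n_p * fp[["pd"]])
  }
  if (n_d > 0)
    out[[length(out) + 1]] <- list(to = c(n_p, n_d - 1),
                                   rate = params$gamma * n_d)
  out[vapply(out, function(e) e$rate > 0, logical(1))]
}

# total-variation distance between an empirical size distribution and a
# model pmf over sizes 0..n_max (+ lumped boundary)
tv_distance_sizes <- function(sizes, bs) {
  n_max <- max(bs$size)
  emp <- tabulate(pmin(sizes, n_max + 1) + 1L, n_max + 2L) / length(sizes)
  mod <- c(bs$prob, attr(bs, "boundary_mass"))
  0.5 * sum(abs(emp - mod))
}

# deterministic replicator ODE for a single advantaged clone frequency
replicator_freq <- function(f0, lam, delta, t) {
  # df/dt = lam * delta * f (1 - f)  =>  logistic
  e <- exp(lam * delta * t)
  f0 * e / (1 - f0 + f0 * e)
}

# exact mean-field of the simulated Moran scheme (events at rate lam * N,
# divider proportional to count * (1 + s)): df/dt = lam s f(1-f)/(1+s f);
# reduces to the replicator ODE as s -> 0.  Integrated by RK4.
moran_mean_field_freq <- function(f0, lam, s, t_grid) {
  rhs <- function(f) lam * s * f * (1 - f) / (1 + s * f)
  f <- f0
  out <- numeric(length(t_grid))
  out[1] <- f0
  for (i in seq_along(t_grid)[-1]) {
    h <- (t_grid[i] - t_grid[i - 1]) / 50
    for (j in 1:50) {
      k1 <- rhs(f); k2 <- rhs(f + h * k1 / 2)
      k3 <- rhs(f + h * k2 / 2); k4 <- rhs(f + h * k3)
      f <- f + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    out[i] <- f
  }
  out
}

# small clone table builder (valid for zero-row tables too)
clone_table <- function(time_weeks, n_basal, n_suprabasal = 0,
                        genotype = "wt", animal_id = "A1") {
  n <- length(time_weeks)
  data.frame(animal_id = rep_len(animal_id, n),
             genotype = rep_len(genotype, n),
             time_weeks = time_weeks, n_basal = n_basal,
             n_suprabasal = rep_len(n_suprabasal, n))
}

# small variant record builder
vrec <- function(chrom = "chr1", pos, ref = "C", alt = "T", biopsy_id,
                 mouse_id, exposure, p_value = 1e-6, fwd = 5, rev = 5) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             biopsy_id = biopsy_id, mouse_id = mouse_id,
             exposure = exposure, p_value = p_value,
             fwd_reads = fwd, rev_reads = rev)
}
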