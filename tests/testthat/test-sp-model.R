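test_that("parameter validation enforces probability constraints", {
  expect_error(sp_params(r = 0), "'r'")
  expect_error(sp_params(r = 0.6), "'r'")
  expect_error(sp_params(r = 0.25, delta = 0.9), "fate probabilities")
  expect_error(sp_params(lam = -1), "'lam'")
  fp <- fate_probs(sp_params(r = 0.3, delta = 0.1))
  expect_equal(unname(fp), c(0.35, 0.4, 0.25))
  expect_equal(sum(fp), 1)
  # delta = 0 recovers the balanced model: PP and DD probabilities equal
  fp0 <- fate_probs(sp_params(r = 0.22))
  expect_equal(fp0[["pp"]], fp0[["dd"]])
})

test_that("parameters round-trip through the key-value config", {
  p <- sp_params(r = 0.31, lam = 2.5, delta = -0.05, gamma = 4.2, mu = 0.7)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sp_params(p, path)
  q <- read_sp_params(path)
  for (f in c("r", "lam", "delta", "gamma", "mu"))
    expect_equal(q[[f]], p[[f]])
  expect_error(read_sp_params(withr::local_tempfile(lines = "r = 0.2")),
               "missing keys")
})

test_that("generator rates match brute-force event enumeration", {
  params <- sp_params(r = 0.25, lam = 1, delta = 0, gamma = 3, mu = 1)
  gen <- sp_generator(params, 6)
  idx <- gen$space$index
  Q <- as.matrix(gen$Q)
  # every off-diagonal rate out of every interior state agrees with the
  # stoichiometry written down by hand
  st <- gen$space$states
  for (i in seq_len(nrow(st))) {
    if (st$n_p[i] + st$n_d[i] >= 5) next   # keep targets inside truncation
    expected <- sp_rates_by_hand(params, st$n_p[i], st$n_d[i])
    row <- Q[i, ]
    for (e in expected) {
      j <- idx(e$to[1], e$to[2])
      expect_equal(unname(row[j]), e$rate)
    }
    expect_equal(unname(-row[i]),
                 sum(vapply(expected, `[[`, numeric(1), "rate")))
  }
  # spot values from the spec of the process
  expect_equal(Q[idx(1, 0), idx(2, 0)], 0.25)        # PP at rate r * lam
  expect_equal(-Q[idx(1, 0), idx(1, 0)], 1)          # single progenitor
})

test_that("generator with lam = 0 contains only stratification events", {
  gen <- sp_generator(sp_params(lam = 0, gamma = 2), 5)
  Q <- as.matrix(gen$Q)
  st <- gen$space$states
  idx <- gen$space$index
  off <- Q; diag(off) <- 0
  for (i in seq_len(nrow(st))) {
    nz <- which(off[i, ] > 0)
    if (st$n_d[i] == 0) expect_length(nz, 0)
    else expect_equal(nz, idx(st$n_p[i], st$n_d[i] - 1))
  }
})

test_that("master-equation pmf conserves mass and starts as a point mass", {
  p <- sp_params()
  pmf <- clone_size_pmf(p, c(0, 1.5, 3, 6), n_max = 50)
  expect_equal(colSums(pmf$P), rep(1, 4), tolerance = 1e-6)
  expect_equal(pmf$P[pmf$space$index(1, 0), 1], 1)
  # boundary mass is reported, not silently dropped
  expect_true(all(pmf$boundary_mass >= 0))
  # a too-small truncation triggers the boundary warning
  expect_warning(clone_size_pmf(sp_params(delta = 0.25), 12, n_max = 20),
                 "boundary mass")
})

test_that("pmf agrees with Gillespie simulation (total variation)", {
  grid <- list(sp_params(r = 0.2, lam = 1.2, delta = 0),
               sp_params(r = 0.3, lam = 1.2, delta = 0.15, gamma = 2))
  for (p in grid) {
    sim <- simulate_clone_final(p, 3, 2e4, seed = 42)
    bs <- basal_size_pmf(clone_size_pmf(p, 3, n_max = 60))
    expect_lt(tv_distance_sizes(sim$n_p + sim$n_d, bs), 0.02)
  }
})

test_that("fast stratification reduces to the critical birth-death process", {
  # Gamma -> inf, delta = 0: progenitor dynamics are a critical
  # birth-death process with rate r * lam
  p <- sp_params(r = 0.25, lam = 1.2, delta = 0, gamma = 2000, mu = 1)
  b <- 0.25 * 1.2
  ex <- extinction_probability(p, c(1, 4), n_max = 40)
  expect_lt(max(abs(ex - bd_extinction_critical(b, c(1, 4)))), 1e-3)
  st <- surviving_clone_size_stats(p, 4, n_max = 60)
  expect_equal(st$mean_basal, bd_surviving_mean_critical(b, 4),
               tolerance = 0.02)
})

test_that("extinction probability is monotone in time and in fate bias", {
  p <- sp_params()
  ex <- extinction_probability(p, c(0, 0.5, 1, 2, 4, 8), n_max = 50)
  expect_equal(ex[1], 0)
  expect_true(all(diff(ex) > 0))
  # strictly decreasing in delta at fixed t
  exd <- vapply(c(-0.1, 0, 0.1, 0.25), function(d)
    extinction_probability(sp_params(delta = d), 4, n_max = 50), numeric(1))
  expect_true(all(diff(exd) < 0))
  # supercritical survival: long-time extinction strictly below 1,
  # approaching the generating-function fixed point
  pb <- sp_params(delta = 0.25)
  exl <- extinction_probability(pb, 30, n_max = 80, boundary_tol = 1)
  expect_lt(exl, 1)
  expect_equal(exl, branching_extinction_limit(0.25, 0.25), tolerance = 0.02)
})

test_that("Gillespie paths honour degenerate parameter limits", {
  # no events at all
  path <- simulate_clone(sp_params(r = 0.25, lam = 0, gamma = 0, mu = 0),
                         t_end = 5, init = c(2, 1, 3), seed = 1)
  expect_equal(nrow(path), 2)
  expect_equal(unlist(path[2, -1]), c(n_p = 2, n_d = 1, n_s = 3))
  # p_DD = 1: first division deterministically yields (0, 2, 0)
  pdd <- sp_params(r = 0.5, delta = -1, lam = 1, gamma = 0, mu = 0)
  for (s in 1:5) {
    path <- simulate_clone(pdd, t_end = 50, seed = s)
    expect_equal(unlist(path[2, -1]), c(n_p = 0, n_d = 2, n_s = 0))
  }
  # reproducibility: identical seed, identical path
  p1 <- simulate_clone(sp_params(), 4, seed = 9)
  p2 <- simulate_clone(sp_params(), 4, seed = 9)
  expect_identical(p1, p2)
})

test_that("balanced progenitor number is a martingale", {
  sim <- simulate_clone_final(sp_params(), 4, 2e4, seed = 3)
  se <- sd(sim$n_p) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$n_p) - 1), 3 * se)
})

test_that("closed-form means match the master equation and Monte Carlo", {
  p0 <- sp_params()
  expect_equal(mean_counts(p0, c(1, 5, 20))[, "n_p"], rep(1, 3))
  pb <- sp_params(delta = 0.2, lam = 1)
  expect_equal(unname(mean_counts(pb, 5)[, "n_p"]), exp(1))
  # gamma = 0: suprabasal decays exponentially from its start
  pg <- sp_params(gamma = 0, mu = 0.5)
  expect_equal(unname(mean_counts(pg, 3, init = c(1, 0, 4))[, "n_s"]),
               4 * exp(-1.5))
  # master-equation means agree with the closed form
  pmf <- clone_size_pmf(pb, 5, n_max = 80)
  st <- pmf$space$states
  m_np <- sum(st$n_p * pmf$P[seq_len(nrow(st)), 1])
  expect_equal(m_np, exp(1), tolerance = 1e-3)
  # Monte-Carlo cross-check
  sim <- simulate_clone_final(pb, 5, 2e4, seed = 5)
  se <- sd(sim$n_p) / sqrt(nrow(sim))
  expect_lt(abs(mean(sim$n_p) - exp(1)), 3 * se)
})

test_that("surviving clone sizes grow and are stochastically larger with bias", {
  p <- sp_params()
  st <- surviving_clone_size_stats(p, c(1.5, 3, 6), n_max = 60)
  expect_true(all(diff(st$mean_basal) > 0))
  expect_equal(surviving_clone_size_stats(p, 0, n_max = 20)$mean_basal, 1)
  # biased conditional mean strictly larger at equal time
  sb <- surviving_clone_size_stats(sp_params(delta = 0.2), 6, n_max = 80)
  expect_gt(sb$mean_basal, st$mean_basal[3])
  expect_error(surviving_clone_size_stats(sp_params(), 1e-12,
                                          detection_min = 5, n_max = 20),
               "degenerate")
})
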