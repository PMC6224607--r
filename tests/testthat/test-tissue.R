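test_that("homeostatic wild type is a fixed point of the tissue model", {
  tp <- tissue_params(init_mutant_fraction = 0)
  tr <- simulate_mean_field(tp, seq(0, 52, by = 1))
  for (col in c("P_wt", "D_wt", "S_wt"))
    expect_equal(tr[[col]], rep(tr[[col]][1], nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$basal_frac, rep(0, nrow(tr)))
  expect_equal(tr$thickness, rep(tr$thickness[1], nrow(tr)),
               tolerance = 1e-8)
  expect_error(tissue_params(wt = sp_params(delta = 0.1)), "homeostatic")
})

test_that("a neutral mutant keeps the labelled basal fraction constant", {
  tp <- tissue_params(init_mutant_fraction = 0.05)   # mutant identical to wt
  tr <- simulate_mean_field(tp, seq(0, 24, by = 0.5))
  expect_equal(tr$basal_frac, rep(0.05, nrow(tr)), tolerance = 1e-8)
  # labelled suprabasal fraction relaxes to the same value
  expect_equal(tr$supra_frac[nrow(tr)], 0.05, tolerance = 1e-4)
})

test_that("mutant basal density matches the clone-level first moment", {
  tp <- tissue_params(mut = sp_params(delta = 0.2),
                      init_mutant_fraction = 0.01)
  tr <- simulate_mean_field(tp, seq(0, 12, by = 0.5))
  B_mut <- tr$P_mut + tr$D_mut
  # progenitor density follows exp(lam * delta * t) exactly
  expect_equal(tr$P_mut / tr$P_mut[1],
               exp(1.2 * 0.2 * tr$time_weeks), tolerance = 1e-6)
  expect_true(all(diff(B_mut) > 0))
})

test_that("labelled fractions stay within [0, 1] across parameter sets", {
  cases <- list(
    tissue_params(mut = sp_params(delta = 0.3), init_mutant_fraction = 0.2),
    tissue_params(mut = sp_params(delta = 0.2, mu = 0.1),
                  init_mutant_fraction = 0.01),
    tissue_params(mut = sp_params(delta = -0.1), init_mutant_fraction = 0.5),
    tissue_params(mut = sp_params(delta = 0.25, gamma = 0.5),
                  init_mutant_fraction = 0.05, feedback_strength = 1))
  for (tp in cases) {
    tr <- simulate_mean_field(tp, seq(0, 36, by = 1))
    expect_true(all(tr$basal_frac >= 0 & tr$basal_frac <= 1 + 1e-9))
    expect_true(all(tr$supra_frac >= 0 & tr$supra_frac <= 1 + 1e-9))
    expect_true(all(tr[, 2:7] >= -1e-9))
  }
})

test_that("reduced mutant shedding lifts the suprabasal fraction above basal", {
  tp <- tissue_params(mut = sp_params(delta = 0.2, mu = 0.2),
                      init_mutant_fraction = 0.01)
  tr <- simulate_mean_field(tp, seq(0, 12, by = 0.25))
  n <- nrow(tr)
  expect_gt(tr$supra_frac[n], tr$basal_frac[n])
  # and the tissue thickens progressively
  th <- thickness_proxy(tr)
  expect_true(all(diff(th[tr$time_weeks >= 1]) > 0))
  # without the shedding change the suprabasal fraction lags the basal one
  tp2 <- tissue_params(mut = sp_params(delta = 0.2),
                       init_mutant_fraction = 0.01)
  tr2 <- simulate_mean_field(tp2, seq(0, 12, by = 0.25))
  expect_lt(tr2$supra_frac[n], tr2$basal_frac[n])
})

test_that("restoring shedding mid-course reverses the thickening", {
  tp <- tissue_params(mut = sp_params(delta = 0.2, mu = 0.2),
                      init_mutant_fraction = 0.01)
  tr1 <- simulate_mean_field(tp, seq(0, 24, by = 0.25))
  y_end <- unlist(tr1[nrow(tr1), 2:7])
  names(y_end) <- c("P_wt", "D_wt", "S_wt", "P_mut", "D_mut", "S_mut")
  # second phase: mutant shedding restored to wild type, fate rebalanced
  tp2 <- tissue_params(mut = sp_params(delta = 0), init_mutant_fraction = 0.01)
  tr2 <- simulate_mean_field(tp2, seq(0, 24, by = 0.25), init = y_end)
  th2 <- thickness_proxy(tr2)
  expect_lt(th2[length(th2)], th2[1])
  expect_true(all(diff(th2) < 1e-9))
})

test_that("crowding feedback attenuates mutant expansion at late times", {
  t_grid <- seq(0, 36, by = 0.5)
  free <- simulate_mean_field(
    tissue_params(mut = sp_params(delta = 0.2), init_mutant_fraction = 0.01),
    t_grid)
  fed <- simulate_mean_field(
    tissue_params(mut = sp_params(delta = 0.2), init_mutant_fraction = 0.01,
                  feedback_strength = 2), t_grid)
  expect_lt(fed$basal_frac[length(t_grid)], free$basal_frac[length(t_grid)])
  # growth rate of the mutant fraction declines as density rises
  g <- diff(log(fed$P_mut))
  expect_lt(g[length(g)], g[1])
})

test_that("only fate imbalance with reduced shedding passes all signatures", {
  scan <- hypothesis_scan()
  expect_setequal(scan$hypothesis,
                  c("symmetric_change", "stratification_decrease",
                    "shedding_decrease", "fate_imbalance",
                    "imbalance_plus_shedding"))
  expect_identical(scan$hypothesis[scan$all_signatures],
                   "imbalance_plus_shedding")
  # per-hypothesis qualitative pattern
  row <- function(h) scan[scan$hypothesis == h, ]
  expect_false(row("stratification_decrease")$basal_rise)
  expect_true(row("fate_imbalance")$basal_rise)
  expect_false(row("fate_imbalance")$thickening)
  expect_error(hypothesis_scan(hypotheses = "made_up"), "unknown hypothesis")
})

test_that("trajectories export to tidy long format", {
  tp <- tissue_params(init_mutant_fraction = 0.01)
  tr <- simulate_mean_field(tp, seq(0, 4, by = 1))
  td <- tidy_trajectory(tr)
  expect_named(td, c("time_weeks", "genotype", "compartment", "density"))
  expect_equal(nrow(td), 6 * nrow(tr))
  expect_equal(td$density[td$genotype == "wt" & td$compartment == "P" &
                            td$time_weeks == 0], tr$P_wt[1])
})
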