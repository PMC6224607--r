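test_that("population size is conserved and runs are reproducible", {
  cfg <- competition_config(n_cells = 800, t_end = 10)
  r1 <- run_competition(cfg, seed = 4)
  r2 <- run_competition(cfg, seed = 4)
  expect_true(all(rowSums(r1$counts) == 800))
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$registry, r2$registry)
  r3 <- run_competition(cfg, seed = 5)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("neutral transgenic frequency is a martingale", {
  cfg <- competition_config(n_cells = 500, f0 = 0.02, delta0 = 0,
                            mut_rate = 0, n_preseed = 0, t_end = 12)
  finals <- vapply(1:200, function(s) {
    tf <- transgenic_lineage_frequency(run_competition(cfg, seed = s))
    tf$frequency[nrow(tf)]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.02), 3 * se)
})

test_that("neutral fixation probability equals the initial frequency", {
  set.seed(99)
  for (k0 in c(1, 5)) {
    p <- moran_fixation_sim(12, k0, s = 0, n_reps = 3000)
    expect_lt(abs(p - k0 / 12), 3 * sqrt((k0 / 12) * (1 - k0 / 12) / 3000))
  }
})

test_that("selective fixation matches the exact absorbing-chain solution", {
  exact <- moran_fixation_exact(10, 1, 0.5)
  # sanity of the oracle itself against the standard closed form
  expect_equal(exact, (1 - (1 / 1.5)^1) / (1 - (1 / 1.5)^10),
               tolerance = 1e-10)
  p <- moran_fixation_sim(10, 1, 0.5, n_reps = 4000, seed = 7)
  expect_lt(abs(p - exact), 3 * sqrt(exact * (1 - exact) / 4000))
})

test_that("selection without mutation follows the mean-field ODE", {
  cfg <- competition_config(n_cells = 2000, f0 = 0.05, delta0 = 0.3,
                            mut_rate = 0, n_preseed = 0, t_end = 10,
                            record_interval = 2)
  freqs <- sapply(1:60, function(s)
    transgenic_lineage_frequency(run_competition(cfg, seed = s))$frequency)
  m <- rowMeans(freqs)
  times <- seq(0, 10, by = 2)
  se <- apply(freqs, 1, sd) / sqrt(ncol(freqs))
  # exact mean-field of the scheme: df/dt = lam s f(1-f)/(1+s f)
  pred <- moran_mean_field_freq(0.05, 1.2, 0.3, times)
  expect_true(all(abs(m - pred) < 3 * se + 0.005))
  expect_true(all(diff(m) > 0))
  # the logistic replicator ODE is recovered in the small-bias regime
  cfg2 <- competition_config(n_cells = 2000, f0 = 0.05, delta0 = 0.1,
                             mut_rate = 0, n_preseed = 0, t_end = 10,
                             record_interval = 5)
  freqs2 <- sapply(1:40, function(s)
    transgenic_lineage_frequency(run_competition(cfg2, seed = s))$frequency)
  m2 <- rowMeans(freqs2)
  pred2 <- replicator_freq(0.05, 1.2, 0.1, c(0, 5, 10))
  se2 <- apply(freqs2, 1, sd) / sqrt(ncol(freqs2))
  expect_true(all(abs(m2 - pred2) < 3 * se2 + 0.005))
})

test_that("lineage bookkeeping covers descendants and detects orphans", {
  cfg <- competition_config(n_cells = 500, t_end = 20, mut_rate = 0.01)
  run <- run_competition(cfg, seed = 11)
  reg <- run$registry
  # mutant descendants of the transgenic clone stay in the lineage
  kids <- reg[!is.na(reg$parent_id) & reg$parent_id == 2, ]
  if (nrow(kids)) expect_true(all(kids$is_transgenic_lineage))
  tf <- transgenic_lineage_frequency(run)
  own <- run$counts[, 2] / 500
  expect_true(all(tf$frequency >= own - 1e-12))
  expect_true(all(tf$frequency >= 0 & tf$frequency <= 1))
  # no mutations ever: lineage frequency is the clone's own frequency
  cfg0 <- competition_config(n_cells = 500, t_end = 10, mut_rate = 0,
                             n_preseed = 0)
  run0 <- run_competition(cfg0, seed = 12)
  expect_equal(transgenic_lineage_frequency(run0)$frequency,
               run0$counts[, 2] / 500)
  bad <- run0
  bad$registry$parent_id[2] <- 99L
  expect_error(transgenic_lineage_frequency(bad), "orphan")
})

test_that("muller table round-trips the frequency series", {
  run <- run_competition(competition_config(n_cells = 400, t_end = 15),
                         seed = 21)
  mt <- muller_table(run)
  sums <- as.numeric(tapply(mt$frequency, mt$time_weeks, sum))
  expect_equal(sums, rep(1, length(run$times)), tolerance = 1e-12)
  # pivoting back reconstructs the counts matrix exactly
  back <- matrix(mt$frequency[order(mt$clone_id, mt$time_weeks)],
                 nrow = length(run$times))
  expect_equal(back * run$config$n_cells,
               matrix(as.numeric(run$counts), nrow = length(run$times)))
  # parents precede their children in the ordering at each timepoint
  reg <- run$registry
  pos <- match(reg$clone_id, sort(reg$clone_id))
  kids <- which(!is.na(reg$parent_id))
  expect_true(all(pos[kids] > pos[reg$parent_id[kids]]))
})

test_that("run summaries flag rise-then-fall correctly", {
  # deterministic-ish: strong selection without mutation rises and stays
  cfg_up <- competition_config(n_cells = 1000, delta0 = 0.3, mut_rate = 0,
                               n_preseed = 0, t_end = 30)
  runs_up <- lapply(1:10, function(s) run_competition(cfg_up, seed = s))
  s_up <- summarize_runs(runs_up)
  expect_true(all(s_up$peak_frequency > 0.02))
  expect_lt(mean(s_up$rose_then_fell), 0.5)
  # neutral runs: the flag fires at most at its false-positive level
  cfg_n <- competition_config(n_cells = 1000, delta0 = 0, mut_rate = 0,
                              n_preseed = 0, t_end = 30)
  runs_n <- lapply(1:50, function(s) run_competition(cfg_n, seed = s))
  s_n <- summarize_runs(runs_n)
  expect_lt(mean(s_n$rose_then_fell), 0.35)
})

test_that("run outputs serialise to delimited text with provenance", {
  run <- run_competition(competition_config(n_cells = 200, t_end = 5),
                         seed = 31)
  base <- file.path(withr::local_tempdir(), "run")
  paths <- write_competition_run(run, base)
  expect_true(all(file.exists(paths)))
  meta <- read_kv(paths[3])
  expect_equal(as.numeric(meta$seed), 31)
  expect_equal(as.integer(meta$n_cells), 200)
  reg <- read.delim(paths[2])
  expect_equal(nrow(reg), nrow(run$registry))
})
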