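test_that("paired-shared removal is symmetric and exposure-aware", {
  # 10 records: 2 variants shared between the paired biopsies of M1
  # (4 records) and 6 private records
  shared <- rbind(
    vrec(pos = 100, biopsy_id = "M1_irr", mouse_id = "M1",
         exposure = "irradiated"),
    vrec(pos = 100, biopsy_id = "M1_un", mouse_id = "M1",
         exposure = "unexposed"),
    vrec(pos = 200, biopsy_id = "M1_irr", mouse_id = "M1",
         exposure = "irradiated"),
    vrec(pos = 200, biopsy_id = "M1_un", mouse_id = "M1",
         exposure = "unexposed"))
  private <- rbind(
    vrec(pos = 300, biopsy_id = "M1_irr", mouse_id = "M1",
         exposure = "irradiated"),
    vrec(pos = 400, biopsy_id = "M1_un", mouse_id = "M1",
         exposure = "unexposed"),
    # same site in two different mice: retained (pairing is per mouse)
    vrec(pos = 100, biopsy_id = "M2_irr", mouse_id = "M2",
         exposure = "irradiated"),
    vrec(pos = 500, biopsy_id = "M2_un", mouse_id = "M2",
         exposure = "unexposed"),
    # same site twice in the same exposure arm of a mouse: retained
    vrec(pos = 600, biopsy_id = "M3_irr_a", mouse_id = "M3",
         exposure = "irradiated"),
    vrec(pos = 600, biopsy_id = "M3_irr_b", mouse_id = "M3",
         exposure = "irradiated"))
  out <- drop_paired_shared(rbind(shared, private))
  expect_equal(nrow(out), 6)
  expect_setequal(out$pos, c(300, 400, 100, 500, 600))
  # idempotent
  expect_identical(drop_paired_shared(out), out)
  expect_error(
    drop_paired_shared(vrec(pos = 1, biopsy_id = "b", mouse_id = "M1",
                            exposure = "uv")),
    "ambiguous exposure")
})

test_that("BH q-values reproduce the step-up worked example", {
  expect_equal(bh_adjust(0.05), 0.05)
  p <- c(0.001, 0.02, 0.04, 0.9)
  expect_equal(bh_adjust(p), c(0.004, 0.04, 4 * 0.04 / 3, 0.9))
  recs <- vrec(pos = 1:4, biopsy_id = "M1_irr", mouse_id = "M1",
               exposure = "irradiated", p_value = 1)
  recs$p_value <- p
  kept <- bh_filter(recs, filter_config(q_max = 0.1))
  expect_equal(kept$pos, 1:3)
  expect_equal(kept$q_value, c(0.004, 0.04, 4 * 0.04 / 3))
  expect_error(bh_filter(within(recs, p_value <- c(0, 0.5, 0.5, 0.5))),
               "p-values")
})

test_that("BH families are formed per mouse, not pooled", {
  p <- c(0.001, 0.02, 0.04, 0.9)
  pooled <- bh_adjust(p)
  recs <- rbind(
    vrec(pos = 1:2, biopsy_id = "M1_irr", mouse_id = "M1",
         exposure = "irradiated"),
    vrec(pos = 3:4, biopsy_id = "M2_irr", mouse_id = "M2",
         exposure = "irradiated"))
  recs$p_value <- p
  out <- bh_filter(recs, filter_config(q_max = 0.1))
  per_mouse <- c(bh_adjust(p[1:2]), bh_adjust(p[3:4]))
  expect_equal(out$q_value, per_mouse[per_mouse < 0.1])
  expect_false(identical(sort(out$q_value),
                         sort(pooled[pooled < 0.1])))
})

test_that("grouped BH matches independent implementations exactly", {
  set.seed(404)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-15)
    expect_lt(max(abs(q - bh_textbook(p))), 1e-12)
  }
})

test_that("strand filter keeps only dual-strand support", {
  recs <- vrec(pos = 1:8, biopsy_id = "M1_irr", mouse_id = "M1",
               exposure = "irradiated")
  recs$fwd_reads <- c(5, 0, 1, 0, 3, 2, 0, 10)
  recs$rev_reads <- c(0, 5, 1, 0, 4, 0, 1, 1)
  out <- strand_filter(recs)
  expect_equal(out$pos, c(3, 5, 8))       # exactly the dual-strand subset
  expect_identical(strand_filter(out), out)
  recs$rev_reads[1] <- NA
  expect_error(strand_filter(recs), "missing strand counts")
})

test_that("the pipeline applies shared, BH, strand in that order", {
  # shared pair with large p-values plus a borderline private record:
  # removing the shared pair first shrinks the BH family so the borderline
  # record survives; running BH first would kill it
  recs <- rbind(
    vrec(pos = 1, biopsy_id = "M1_irr", mouse_id = "M1",
         exposure = "irradiated", p_value = 0.9),
    vrec(pos = 1, biopsy_id = "M1_un", mouse_id = "M1",
         exposure = "unexposed", p_value = 0.9),
    vrec(pos = 2, biopsy_id = "M1_irr", mouse_id = "M1",
         exposure = "irradiated", p_value = 0.09))
  out <- run_filter_pipeline(recs)
  expect_equal(out$records$pos, 2)
  wrong_order <- strand_filter(drop_paired_shared(bh_filter(recs)))
  expect_equal(nrow(wrong_order), 0)
  # attrition bookkeeping: input = output + removed per stage
  expect_equal(out$attrition$n_in[1],
               out$attrition$n_out[3] + sum(out$attrition$n_removed))
  expect_equal(out$attrition$n_removed, c(2, 0, 0))
  # empty input passes through with a zero report
  e <- run_filter_pipeline(recs[0, ])
  expect_equal(nrow(e$records), 0)
  expect_equal(e$attrition$n_in, c(0, 0, 0))
})

test_that("mutation burden is variants per square millimetre", {
  recs <- rbind(
    vrec(pos = 1:5, biopsy_id = "B1", mouse_id = "M1",
         exposure = "irradiated"),
    vrec(pos = 1:11, biopsy_id = "B2", mouse_id = "M1",
         exposure = "unexposed"))
  mb <- mutation_burden(recs)
  expect_equal(mb$burden_per_mm2[mb$biopsy_id == "B1"], 5 / 16)
  expect_equal(mb$burden_per_mm2[mb$biopsy_id == "B2"], 11 / 16)
  # 32 variants in one 16-mm^2 biopsy: 2 per mm^2; empty biopsy reports 0
  recs32 <- vrec(pos = 1:32, biopsy_id = "B3", mouse_id = "M2",
                 exposure = "irradiated")
  all_b <- data.frame(biopsy_id = c("B3", "B4"), mouse_id = "M2",
                      exposure = c("irradiated", "unexposed"))
  mb2 <- mutation_burden(recs32, all_biopsies = all_b)
  expect_equal(mb2$burden_per_mm2, c(2, 0))
})

test_that("mutational spectrum collapses strands to pyrimidine context", {
  one <- vrec(pos = 1, ref = "G", alt = "A", biopsy_id = "B",
              mouse_id = "M1", exposure = "irradiated")
  s1 <- mutation_spectrum(one)
  expect_equal(unname(s1$counts["C>T"]), 1)
  expect_equal(s1$c_to_t_fraction, 1)
  recs <- vrec(pos = 1:4, biopsy_id = "B", mouse_id = "M1",
               exposure = "irradiated")
  recs$ref <- c("C", "C", "T", "G")
  recs$alt <- c("T", "T", "A", "A")
  s <- mutation_spectrum(recs)
  expect_equal(s$c_to_t_fraction, 0.75)
  expect_equal(unname(s$counts["T>A"]), 1)
  expect_equal(sum(s$fractions), 1)
  # non-SNVs are reported, not dropped; empty SNV set flags undefined
  recs$ref[2] <- "CT"
  s2 <- mutation_spectrum(recs)
  expect_equal(nrow(s2$non_snv), 1)
  expect_equal(s2$n_snv, 3)
  s0 <- mutation_spectrum(recs[0, ])
  expect_true(s0$undefined)
  expect_true(is.na(s0$c_to_t_fraction))
})
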