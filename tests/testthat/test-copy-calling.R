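test_that("replicate Cts aggregate within experiments, then across", {
  a <- aggregate_ct(c(25.0, 25.2, 24.8))
  expect_equal(a$mean, 25.0)
  expect_equal(a$n_experiments, 1)

  b <- aggregate_ct(c(25.0, 25.0, 26.0, 26.0), c("e1", "e1", "e2", "e2"))
  expect_equal(b$mean, 25.5)
  expect_equal(b$sd, stats::sd(c(25, 26)))

  s <- aggregate_ct(25.3)
  expect_equal(s$mean, 25.3)
  expect_true(is.na(s$sd))
  expect_true("single_well" %in% s$flags)

  noisy <- aggregate_ct(c(24, 26), c("e1", "e1"), qc_cutoff = 0.5)
  expect_true("high_replicate_sd" %in% noisy$flags)
  expect_error(aggregate_ct(numeric(0)), "no Ct")
})

test_that("standard curve recovers efficiency from dilution series", {
  # perfect doubling: Ct rises by log2(10) per 10-fold dilution
  sc <- fit_standard_curve(c(20.0000, 23.3219, 26.6439), c(1, 0.1, 0.01))
  expect_equal(sc$slope, -log2(10), tolerance = 1e-4)
  expect_equal(sc$efficiency, 2, tolerance = 1e-4)

  expect_error(fit_standard_curve(c(20, 23.3), c(1, 0.1)), ">= 3 distinct")
  expect_error(fit_standard_curve(c(20, 19, 18), c(1, 0.1, 0.01)), "negative")

  # noisy series generated at E = 1.9 recovers E within 0.05
  noise <- qpcr_noise_model(e_target = 1.9, ct_sd = 0.05,
                            dilution_series = c(1, 0.1, 0.01, 0.001))
  ct <- simulate_qpcr(data.frame(sample_id = "S1", assay = "NTRK1", ratio = 1),
                      noise, seed = 42)
  dil <- ct[ct$role == "dilution" & ct$assay == "NTRK1", ]
  sc2 <- fit_standard_curve(dil, assay = "NTRK1")
  expect_lt(abs(sc2$efficiency - 1.9), 0.05)
})

test_that("efficiency-corrected ratio follows the Pfaffl formula", {
  # calibrator identity: all four Cts equal
  expect_equal(efficiency_corrected_ratio(25, 25, 25, 25, 1.9, 1.8), 1.0)
  # one doubling in the target, reference unchanged
  expect_equal(efficiency_corrected_ratio(24, 25, 25, 25, 2, 2), 2.0)
  # direct evaluation with unequal efficiencies
  expect_equal(efficiency_corrected_ratio(24, 25, 24, 25, 1.9, 2.0), 1.9 / 2.0)
  expect_error(efficiency_corrected_ratio(24, 25, 24, 25, 0.9, 2), "exceed 1")
})

test_that("ddCt is the E = 2 special case, exactly", {
  expect_equal(ddct_ratio(25, 25, 25, 25), 1.0)
  expect_equal(ddct_ratio(24, 25, 25, 25), 2.0)  # ddCt = -1
  set.seed(1)
  for (i in 1:25) {
    cts <- runif(4, 18, 32)
    expect_identical(ddct_ratio(cts[1], cts[2], cts[3], cts[4]),
                     efficiency_corrected_ratio(cts[1], cts[2], cts[3], cts[4], 2, 2))
  }
})

test_that("fold-change classification uses the five-state thresholds", {
  expect_equal(as.character(classify_fold_change(1.80)), "AMPLIFICATION")
  expect_equal(as.character(classify_fold_change(1.00)), "DIPLOID")
  expect_equal(as.character(classify_fold_change(0.40)), "HOMOZYGOUS_DELETION")
  # boundary values belong to the non-diploid state
  expect_equal(as.character(classify_fold_change(c(0.5, 0.75, 1.25, 1.75))),
               c("HEMIZYGOUS_DELETION", "HEMIZYGOUS_DELETION", "GAIN", "GAIN"))
  expect_error(classify_fold_change(0), "positive")
})

test_that("classification partitions (0, Inf) monotonically", {
  grid <- c(seq(0.01, 5, by = 0.007), 0.5, 0.75, 1.25, 1.75)
  st <- classify_fold_change(grid)
  expect_false(anyNA(st))
  # monotone non-decreasing state along increasing ratio
  ord <- order(grid)
  expect_true(all(diff(as.integer(st[ord])) >= 0))
  # every state is reachable
  expect_setequal(as.character(unique(st)), copy_states())
})

test_that("segment state calls work on the log2 scale", {
  expect_equal(as.character(call_segment_state(0)), "DIPLOID")
  expect_equal(as.character(call_segment_state(1)), "AMPLIFICATION")
  expect_equal(as.character(call_segment_state(-1.2)), "HOMOZYGOUS_DELETION")
  expect_identical(call_segment_state(0.3), classify_fold_change(2^0.3))
})

test_that("noise-free qPCR pipeline returns planted ratios to machine precision", {
  truth <- data.frame(sample_id = sprintf("S%d", 1:6),
                      assay = "NTRK1",
                      ratio = c(0.3, 0.6, 1.0, 1.4, 2.0, 3.1))
  noise <- qpcr_noise_model(e_target = 1.9, e_ref = 1.95, ct_sd = 0)
  ct <- simulate_qpcr(truth, noise, seed = 5)
  fc <- qpcr_copy_calls(ct)
  got <- fc$ratio[match(truth$sample_id, fc$sample_id)]
  expect_equal(got, truth$ratio, tolerance = 1e-12)
  # classification of planted states is exact when ratios clear thresholds
  expect_equal(fc$state[match(truth$sample_id, fc$sample_id)],
               as.character(classify_fold_change(truth$ratio)))
  # ddct method on E = 2 data is also exact
  ct2 <- simulate_qpcr(truth, qpcr_noise_model(ct_sd = 0), seed = 5)
  fc2 <- qpcr_copy_calls(ct2, method = "ddct")
  expect_equal(fc2$ratio[match(truth$sample_id, fc2$sample_id)], truth$ratio,
               tolerance = 1e-12)
  # mean-of-ratios agrees with aggregated-Ct on noise-free data
  fc3 <- qpcr_copy_calls(ct, combine = "mean_of_ratios")
  expect_equal(fc3$ratio[match(truth$sample_id, fc3$sample_id)], truth$ratio,
               tolerance = 1e-12)
})

test_that("qpcr_copy_calls validates its inputs", {
  truth <- data.frame(sample_id = "S1", assay = "NTRK1", ratio = 2)
  ct <- simulate_qpcr(truth, qpcr_noise_model(ct_sd = 0), seed = 1)
  expect_error(qpcr_copy_calls(ct, reference_assay = "GAPDH"), "absent")
  expect_error(qpcr_copy_calls(ct, calibrator_id = "nope"), "calibrator")
  no_dil <- ct[ct$role != "dilution", ]
  expect_error(qpcr_copy_calls(no_dil), "dilution series")
  expect_equal(qpcr_copy_calls(no_dil, method = "ddct")$ratio, 2, tolerance = 1e-12)
})
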