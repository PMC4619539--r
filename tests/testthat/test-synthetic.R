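test_that("copy-state allocation uses exact quotas and respects spec invariants", {
  spec <- cohort_spec(n_samples = 10,
                      planted_hotspots = data.frame(
                        chrom = "chr1", start = 1e6, end = 2e6,
                        fraction_amplified = 0.5, fraction_gained = 0.2),
                      chrom_lengths = c(chr1 = 1e7), passenger_rate = 0, seed = 3)
  co <- simulate_cohort(spec)
  expect_equal(sum(co$truth$state == "AMPLIFICATION"), 5)
  expect_equal(sum(co$truth$state == "GAIN"), 2)

  # invalid specs are rejected
  expect_error(cohort_spec(planted_hotspots = data.frame(
    chrom = "chr1", start = 1e6, end = 3e8,
    fraction_amplified = 0.2, fraction_gained = 0)), "outside chrom_lengths")
  expect_error(cohort_spec(planted_hotspots = data.frame(
    chrom = "chr1", start = 1e6, end = 2e6,
    fraction_amplified = 0.8, fraction_gained = 0.5)), "<= 1")
})

test_that("passenger_rate = 0 leaves no amplification outside planted loci", {
  spec <- cohort_spec(n_samples = 8, passenger_rate = 0, seed = 5,
                      chrom_lengths = c(chr1 = 5e7),
                      planted_hotspots = data.frame(
                        chrom = "chr1", start = 2e7, end = 2.03e7,
                        fraction_amplified = 0.5, fraction_gained = 0))
  co <- simulate_cohort(spec)
  amp <- amplified_intervals(co$segments)
  # every amplified interval contains the planted locus and nothing else
  expect_true(all(amp$start <= 2e7 & amp$end >= 2.03e7))
  expect_equal(nrow(amp), 4)
})

test_that("segments tile each chromosome without overlap and agree with truth", {
  spec <- cohort_spec(n_samples = 6, seed = 8, chrom_lengths = c(chr1 = 249250621))
  co <- simulate_cohort(spec)
  for (sid in unique(co$segments$sample_id)) {
    s <- co$segments[co$segments$sample_id == sid, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 1)
    expect_equal(s$end[nrow(s)], 249250621)
    if (nrow(s) > 1) expect_true(all(s$start[-1] == s$end[-nrow(s)] + 1))
  }
  # the segment caller reproduces the planted truth at the locus
  st <- locus_states(co$segments, "chr1", 156826196, 157106439)
  tr <- co$truth[match(st$sample_id, co$truth$sample_id), ]
  expect_equal(st$state, tr$state)
})

test_that("one seed reproduces the cohort and the Ct table byte-for-byte", {
  spec <- cohort_spec(n_samples = 5, seed = 21)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)

  tr <- data.frame(sample_id = c("S1", "S2"), assay = "NTRK1", ratio = c(2.2, 0.9))
  c1 <- simulate_qpcr(tr, qpcr_noise_model(ct_sd = 0.2), seed = 13)
  c2 <- simulate_qpcr(tr, qpcr_noise_model(ct_sd = 0.2), seed = 13)
  expect_identical(c1, c2)
  c3 <- simulate_qpcr(tr, qpcr_noise_model(ct_sd = 0.2), seed = 14)
  expect_false(identical(c1, c3))
})

test_that("the Ct generative model has the closed-form structure", {
  # ratio 2 at E = 2: sample Ct exactly one cycle below calibrator
  tr <- data.frame(sample_id = "S1", assay = "NTRK1", ratio = 2)
  ct <- simulate_qpcr(tr, qpcr_noise_model(ct_sd = 0), seed = 1)
  s <- ct[ct$role == "sample" & ct$assay == "NTRK1", "ct"][1]
  cal <- ct[ct$role == "calibrator" & ct$assay == "NTRK1", "ct"][1]
  expect_equal(cal - s, 1)

  # dilution series at E = 2: Ct climbs by log2(10) per 10-fold dilution
  dil <- ct[ct$role == "dilution" & ct$assay == "NTRK1", ]
  m <- tapply(dil$ct, dil$dilution_factor, mean)
  steps <- diff(m[order(as.numeric(names(m)), decreasing = TRUE)])
  expect_equal(as.numeric(steps), rep(log2(10), 3), tolerance = 1e-10)
})

test_that("null survival simulation is calibrated (hr_amp = 1)", {
  # exponential oracle: with equal hazards the groups are exchangeable, so
  # log-rank p is uniform and the MH hazard-ratio estimate centers on 1
  spec <- cohort_spec(n_samples = 100, seed = 1, passenger_rate = 0,
                      chrom_lengths = c(chr1 = 1e7),
                      planted_hotspots = data.frame(
                        chrom = "chr1", start = 4e6, end = 5e6,
                        fraction_amplified = 0.5, fraction_gained = 0))
  null_model <- survival_model(baseline_rate = 0.01, hr_amp = 1, censor_time = Inf)
  ps <- hrs <- numeric(60)
  for (r in seq_len(60)) {
    spec$seed <- 1000 + r
    co <- simulate_cohort(spec, survival = null_model)
    st <- co$truth$state[match(co$clinical$sample_id, co$truth$sample_id)]
    g1 <- co$clinical[st == "AMPLIFICATION", ]
    g2 <- co$clinical[st == "DIPLOID", ]
    cmp <- logrank_and_hr(g1$mfs_time, g1$mfs_event, g2$mfs_time, g2$mfs_event)
    ps[r] <- cmp$logrank_p
    hrs[r] <- cmp$hr
  }
  expect_gt(mean(ps), 0.35)           # roughly uniform p values
  expect_lt(mean(ps), 0.65)
  expect_lt(abs(mean(log(hrs))), 0.15)  # log HR centered at 0
})

test_that("synthetic gene models land inside planted hotspots", {
  spec <- cohort_spec(seed = 2)
  g <- simulate_genes(spec, genes_per_hotspot = 6, n_background = 20, seed = 2)
  planted <- g[grepl("^HS", g$gene_id), ]
  expect_equal(nrow(planted), 6)
  expect_true(all(planted$start >= 156826196 & planted$end <= 157106439))
  expect_true(all(g$start < g$end))
})
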