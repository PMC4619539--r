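mk_seg <- function(sample_id, chrom, start, end, log2_ratio) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             log2_ratio = log2_ratio, stringsAsFactors = FALSE)
}

test_that("amplified intervals keep only amplified segments and merge abutting ones", {
  seg <- rbind(mk_seg("S1", "chr1", 100, 1000, 1.0),
               mk_seg("S1", "chr1", 1500, 2000, 0.0))
  out <- amplified_intervals(seg)
  expect_equal(nrow(out), 1)
  expect_equal(out$end, 1000)

  # two abutting amplified segments merge at merge_gap = 0
  seg2 <- rbind(mk_seg("S1", "chr1", 100, 1000, 1.0),
                mk_seg("S1", "chr1", 1001, 2000, 1.2))
  out2 <- amplified_intervals(seg2)
  expect_equal(nrow(out2), 1)
  expect_equal(c(out2$start, out2$end), c(100, 2000))

  # a 10 bp gap is bridged only when merge_gap allows it
  seg3 <- rbind(mk_seg("S1", "chr1", 100, 1000, 1.0),
                mk_seg("S1", "chr1", 1011, 2000, 1.2))
  expect_equal(nrow(amplified_intervals(seg3)), 2)
  expect_equal(nrow(amplified_intervals(seg3, merge_gap = 10)), 1)

  expect_equal(nrow(amplified_intervals(seg[0, ])), 0)
  # gains count only when asked
  seg4 <- mk_seg("S1", "chr1", 100, 1000, log2(1.5))
  expect_equal(nrow(amplified_intervals(seg4)), 0)
  expect_equal(nrow(amplified_intervals(seg4, include_gain = TRUE)), 1)
})

test_that("support profile equals the distinct-sample depth at every base", {
  amp <- data.frame(sample_id = c("A", "B"), chrom = "chr1",
                    start = c(100, 500), end = c(1000, 1500))
  pr <- build_support_profile(amp, "chr1")
  expect_equal(pr$start, c(100, 500, 1001))
  expect_equal(pr$end, c(499, 1000, 1500))
  expect_equal(pr$depth, c(1L, 2L, 1L))

  # one sample with two overlapping intervals counts once on the overlap
  amp2 <- data.frame(sample_id = "A", chrom = "chr1",
                     start = c(100, 500), end = c(1000, 1500))
  pr2 <- build_support_profile(amp2, "chr1")
  expect_equal(max(pr2$depth), 1L)

  expect_error(build_support_profile(amp, "chr2"), "wrong chromosome")

  # brute-force oracle on a 10 kb toy chromosome
  set.seed(99)
  iv <- random_toy_intervals(n_samples = 10, chrom_len = 1e4, max_per_sample = 5)
  pr3 <- build_support_profile(iv, "chr1")
  depth_fn <- function(b) sum(vapply(split(iv, iv$sample_id),
                                     function(d) any(d$start <= b & d$end >= b),
                                     logical(1)))
  probe <- sort(sample(1e4, 200))
  got <- vapply(probe, function(b) {
    k <- which(pr3$start <= b & pr3$end >= b)
    if (length(k)) pr3$depth[k] else 0L
  }, integer(1))
  expect_equal(got, vapply(probe, depth_fn, integer(1)))
})

test_that("find_hotspots returns the minimal common overlap", {
  # three-way intersection
  amp <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                    start = c(100, 500, 800), end = c(1000, 1500, 1200))
  hs <- find_hotspots(build_support_profile(amp, "chr1"))
  expect_equal(nrow(hs), 1)
  expect_equal(c(hs$start, hs$end), c(800, 1000))
  expect_equal(hs$support, 3L)
  expect_setequal(hs$samples[[1]], c("A", "B", "C"))

  # two samples never make a hotspot at min_support = 3
  hs2 <- find_hotspots(build_support_profile(amp[1:2, ], "chr1"))
  expect_equal(nrow(hs2), 0)

  # a 3 Mb plateau of depth 3 fails the 2.5 Mb filter
  amp3 <- data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
                     start = 1e6, end = 4e6 - 1)
  expect_equal(nrow(find_hotspots(build_support_profile(amp3, "chr1"))), 0)
  expect_equal(nrow(find_hotspots(build_support_profile(amp3, "chr1"),
                                  max_length = 3e6)), 1)

  expect_error(find_hotspots(build_support_profile(amp, "chr1"), min_support = 0),
               "min_support")
})

test_that("find_hotspots matches the brute-force per-base oracle", {
  set.seed(4242)
  for (rep in 1:25) {
    iv <- random_toy_intervals(n_samples = 10, chrom_len = 1e5)
    if (nrow(iv) == 0) next
    pr <- build_support_profile(iv, "chr1")
    got <- as_plain_hotspots(find_hotspots(pr, min_support = 3, max_length = 30000))
    want <- brute_hotspots(iv, 1e5, min_support = 3, max_length = 30000)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("replicate", rep))
  }
})

test_that("hotspots are contained in every supporter's amplicon; support is monotone", {
  set.seed(77)
  for (rep in 1:10) {
    iv <- random_toy_intervals(n_samples = 8, chrom_len = 5e4)
    if (nrow(iv) == 0) next
    pr <- build_support_profile(iv, "chr1")
    hs <- find_hotspots(pr, min_support = 2, max_length = Inf)
    merged <- attr(pr, "amplicons")  # per-sample merged amplified intervals
    for (i in seq_len(nrow(hs))) {
      for (s in hs$samples[[i]]) {
        cover <- merged[merged$sample_id == s & merged$start <= hs$start[i] &
                          merged$end >= hs$end[i], ]
        expect_gte(nrow(cover), 1)
      }
      expect_equal(length(hs$samples[[i]]), hs$support[i])
    }
    # raising min_support never enlarges intervals nor increases the count
    hs3 <- find_hotspots(pr, min_support = 3, max_length = Inf)
    expect_lte(nrow(hs3), nrow(hs))
    for (i in seq_len(nrow(hs3))) {
      inside <- hs$start <= hs3$start[i] & hs$end >= hs3$end[i] |
        (hs$start <= hs3$end[i] & hs$end >= hs3$start[i])
      expect_true(any(inside))
    }
  }
})

test_that("gene annotation uses 1 bp overlap and deduplicates across hotspots", {
  hs <- find_hotspots(build_support_profile(
    data.frame(sample_id = c("A", "B", "C"), chrom = "chr1",
               start = c(100, 150, 200), end = c(300, 320, 340)), "chr1"))
  expect_equal(c(hs$start, hs$end), c(200, 300))
  genes <- data.frame(gene_id = c("g_in", "g_edge", "g_out"),
                      chrom = "chr1",
                      start = c(150, 300, 301), end = c(250, 400, 400),
                      strand = "+")
  ann <- annotate_genes(hs, genes)
  expect_setequal(ann$genes[[1]], c("g_in", "g_edge"))

  # five genes, two hotspots sharing one gene -> 4 unique among 5 assignments
  hs2 <- rbind(hs, hs)
  hs2$start <- c(200, 260); hs2$end <- c(260, 300)
  genes2 <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                       start = c(200, 210, 255, 270, 290),
                       end = c(205, 215, 265, 275, 295), strand = "+")
  ann2 <- annotate_genes(as_hotspot <- structure(hs2, class = class(hs)), genes2)
  expect_equal(sum(lengths(ann2$genes)), 6)  # g3 assigned twice
  expect_equal(n_unique_genes(ann2), 5)
})

test_that("covariate association computes Mann-Whitney contrasts vs diploid", {
  states <- c(rep("AMPLIFICATION", 3), rep("DIPLOID", 3))
  res <- associate_with_covariate(states, c(4, 5, 6, 1, 2, 3),
                                  alternative = "greater")
  amp <- res[res$contrast == "AMPLIFICATION_vs_DIPLOID", ]
  expect_equal(amp$U, 9)            # maximal: every amplified beats every diploid
  expect_equal(amp$p_value, 0.05)   # 1 of the 20 equally likely rank splits
  expect_equal(amp$median_group, 5)
  expect_equal(amp$median_diploid, 2)
  expect_false(res$computable[res$contrast == "GAIN_vs_DIPLOID"])

  # identical covariate values in both groups -> p = 1
  res2 <- associate_with_covariate(states, rep(2, 6))
  expect_equal(res2$p_value[res2$contrast == "AMPLIFICATION_vs_DIPLOID"], 1)
})

test_that("deletion-state support works through the include flag pathway", {
  # gain-inclusive support changes hotspot support counts
  seg <- rbind(mk_seg(c("A", "B", "C"), "chr1", 100, 1000, c(1.0, 1.0, log2(1.5))))
  hs_strict <- detect_hotspots(seg, min_support = 3)
  hs_gain <- detect_hotspots(seg, min_support = 3, include_gain = TRUE)
  expect_equal(nrow(hs_strict), 0)
  expect_equal(nrow(hs_gain), 1)
  expect_equal(hs_gain$support, 3L)
})

test_that("locus states are length-weighted means over the locus", {
  seg <- rbind(mk_seg("S1", "chr1", 1, 100, 1.0),
               mk_seg("S1", "chr1", 101, 200, 0.0),
               mk_seg("S2", "chr1", 1, 200, 0.2))
  st <- locus_states(seg, "chr1", 51, 150)
  # S1: 50 bp at 1.0 and 50 bp at 0.0 -> 0.5
  expect_equal(st$log2_ratio[st$sample_id == "S1"], 0.5)
  expect_equal(st$log2_ratio[st$sample_id == "S2"], 0.2)
})
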