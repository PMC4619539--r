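# Independent oracles used by the property tests. These deliberately share
# no code with the package implementations.

# Brute-force per-base MCR finder on a small chromosome. Every base gets the
# set of distinct covering samples (bitmask); qualifying runs are split into
# blocks of constant (depth, sample set) and locally maximal blocks kept.
brute_hotspots <- function(iv, chrom_len, min_support = 3, max_length = Inf) {
  samples <- sort(unique(iv$sample_id))
  stopifnot(length(samples) <= 30)
  cov <- matrix(FALSE, length(samples), chrom_len)
  for (i in seq_len(nrow(iv)))
    cov[match(iv$sample_id[i], samples), iv$start[i]:iv$end[i]] <- TRUE
  depth <- colSums(cov)
  setid <- as.integer(2^(seq_along(samples) - 1) %*% cov)
  qual <- depth >= min_support
  r <- rle(qual)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  out <- list()
  for (j in which(r$values)) {
    pos <- run_start[j]:run_end[j]
    d <- depth[pos]; k <- setid[pos]
    blk <- cumsum(c(TRUE, d[-1] != d[-length(d)] | k[-1] != k[-length(k)]))
    bidx <- split(seq_along(pos), blk)
    bd <- vapply(bidx, function(ii) d[ii[1]], numeric(1))
    nb <- length(bd)
    left <- c(-Inf, bd[-nb]); right <- c(bd[-1], -Inf)
    for (b in which(bd >= left & bd >= right)) {
      ii <- bidx[[b]]
      s <- pos[ii[1]]; e <- pos[ii[length(ii)]]
      if (e - s + 1 > max_length) next
      supp <- samples[cov[, s]]
      out[[length(out) + 1L]] <- data.frame(start = as.numeric(s), end = as.numeric(e),
                                            support = as.integer(bd[b]),
                                            samples = paste(sort(supp), collapse = ","),
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(), support = integer(),
                      samples = character()))
  out <- do.call(rbind, out)
  out[order(out$start), , drop = FALSE]
}

# random amplified-interval sets for a toy cohort
random_toy_intervals <- function(n_samples = 10, chrom_len = 1e5,
                                 max_per_sample = 5, chrom = "chr1") {
  rows <- list()
  for (s in seq_len(n_samples)) {
    k <- sample(0:max_per_sample, 1)
    if (k == 0) next
    w <- sample(50:floor(chrom_len / 5), k, replace = TRUE)
    st <- vapply(w, function(wi) sample.int(chrom_len - wi, 1), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("T%02d", s), chrom = chrom,
      start = st, end = st + w, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  do.call(rbind, rows)
}

# closed-form empirical survival (no censoring): S(t) = #(T > t) / n
empirical_survival <- function(times, t) vapply(t, function(x) mean(times > x), numeric(1))

# hotspot tables as comparable plain frames
as_plain_hotspots <- function(hs) {
  data.frame(start = hs$start, end = hs$end, support = hs$support,
             samples = vapply(hs$samples, function(x) paste(sort(x), collapse = ","), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
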