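#' Per-sample amplified intervals from segment calls
#'
#' Classifies each segment with [call_segment_state()] and keeps, per
#' sample, the intervals in amplified state (optionally also single-copy
#' gains). Adjacent kept intervals of one sample are merged when the gap
#' between them is at most `merge_gap` bp (abutting segments have gap 0).
#'
#' @param segments segment table (see [read_segments()]).
#' @param thresholds fold-change thresholds for the segment caller.
#' @param merge_gap maximum gap (bp) bridged when merging, default 0.
#' @param include_gain also count GAIN segments as support.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`.
#' @export
amplified_intervals <- function(segments, thresholds = copy_state_thresholds(),
                                merge_gap = 0, include_gain = FALSE) {
  keep_states <- if (include_gain) c("AMPLIFICATION", "GAIN") else "AMPLIFICATION"
  if (nrow(segments) == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  st <- call_segment_state(segments$log2_ratio, thresholds)
  amp <- segments[st %in% keep_states, c("sample_id", "chrom", "start", "end"),
                  drop = FALSE]
  if (nrow(amp) == 0) return(amp)
  amp <- amp[order(amp$sample_id, amp$chrom, amp$start), , drop = FALSE]
  merged <- lapply(split(amp, list(amp$sample_id, amp$chrom), drop = TRUE),
                   merge_intervals, max_gap = merge_gap)
  out <- do.call(rbind, merged)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# merge sorted intervals of one sample on one chromosome; gaps <= max_gap
# are bridged (overlaps always merged)
merge_intervals <- function(df, max_gap = 0) {
  if (nrow(df) < 2) return(df)
  df <- df[order(df$start), , drop = FALSE]
  s <- df$start; e <- df$end
  out_s <- s[1]; out_e <- e[1]
  for (i in 2:nrow(df)) {
    if (interval_gap(out_e[length(out_e)], s[i]) <= max_gap) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  data.frame(sample_id = df$sample_id[1], chrom = df$chrom[1],
             start = out_s, end = out_e, stringsAsFactors = FALSE)
}

#' Build the support profile of one chromosome
#'
#' Sweep-line computation of the piecewise-constant amplification depth: at
#' every base, the depth is the number of distinct samples whose amplified
#' intervals cover it. Intervals of one sample are merged first so a sample
#' never counts twice at a position.
#'
#' @param amplicons per-sample amplified intervals (from
#'   [amplified_intervals()]); all rows must be on `chrom`.
#' @param chrom chromosome to profile.
#' @return an object of class `support_profile`: a data.frame of elementary
#'   steps (`start`, `end`, `depth`) with per-step supporting sample sets in
#'   `attr(, "step_samples")` and the merged per-sample intervals in
#'   `attr(, "amplicons")`.
#' @export
build_support_profile <- function(amplicons, chrom) {
  if (nrow(amplicons) && any(amplicons$chrom != chrom))
    stop("amplicons on wrong chromosome passed to build_support_profile")
  empty <- data.frame(start = numeric(), end = numeric(), depth = integer())
  if (nrow(amplicons) == 0)
    return(structure(empty, chrom = chrom, step_samples = list(),
                     amplicons = amplicons, class = c("support_profile", "data.frame")))
  merged <- do.call(rbind, lapply(split(amplicons, amplicons$sample_id),
                                  merge_intervals, max_gap = 0))
  # event sweep: +1 at start, -1 at end + 1 (1-based inclusive intervals)
  bp <- sort(unique(c(merged$start, merged$end + 1)))
  step_start <- bp[-length(bp)]
  step_end <- bp[-1] - 1
  n_steps <- length(step_start)
  depth <- integer(n_steps)
  step_samples <- replicate(n_steps, character(0), simplify = FALSE)
  for (i in seq_len(nrow(merged))) {
    first <- findInterval(merged$start[i], step_start)
    last <- findInterval(merged$end[i], step_start)
    for (k in first:last) {
      depth[k] <- depth[k] + 1L
      step_samples[[k]] <- c(step_samples[[k]], merged$sample_id[i])
    }
  }
  out <- data.frame(start = step_start, end = step_end, depth = depth)
  structure(out, chrom = chrom, step_samples = step_samples, amplicons = merged,
            class = c("support_profile", "data.frame"))
}

#' @export
print.support_profile <- function(x, ...) {
  cat(sprintf("Support profile on %s: %d steps, max depth %d\n",
              attr(x, "chrom"), nrow(x), if (nrow(x)) max(x$depth) else 0L))
  invisible(x)
}

#' Find minimal common regions of amplification
#'
#' Within every maximal run of depth >= `min_support`, the hotspot is the
#' locally deepest plateau: a deeper sub-region is shared by more samples
#' and is by construction the minimal common overlap of that larger
#' supporting set. Adjacent equal-depth steps are merged into one plateau
#' when their supporting sample sets coincide. Hotspots longer than
#' `max_length` bp are discarded. The defaults encode the recurrence rule
#' used for the melanoma cohort: at least three supporting samples and at
#' most 2.5 Mb.
#'
#' @param profile a `support_profile` from [build_support_profile()].
#' @param min_support minimum number of distinct supporting samples (>= 1).
#' @param max_length maximum hotspot length in bp.
#' @return an object of class `hotspot_set`: data.frame with columns
#'   `chrom`, `start`, `end`, `length_bp`, `support` and list column
#'   `samples`, sorted by (chrom, start).
#' @export
find_hotspots <- function(profile, min_support = 3, max_length = 2.5e6) {
  if (min_support < 1) stop("min_support must be >= 1")
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_bp = numeric(), support = integer())
  empty$samples <- list()
  if (nrow(profile) == 0) return(as_hotspot_set(empty))
  step_samples <- attr(profile, "step_samples")
  chrom <- attr(profile, "chrom")

  qual <- profile$depth >= min_support
  runs <- rle(qual)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  hs <- list()
  for (r in which(runs$values)) {
    idx <- run_start[r]:run_end[r]
    # collapse adjacent steps with equal depth AND identical supporter sets
    plat <- list()
    cur <- idx[1]
    cur_set <- sort(step_samples[[cur]])
    p_start <- profile$start[cur]; p_end <- profile$end[cur]
    p_depth <- profile$depth[cur]
    for (k in idx[-1]) {
      set_k <- sort(step_samples[[k]])
      if (profile$depth[k] == p_depth && identical(set_k, cur_set) &&
          profile$start[k] == p_end + 1) {
        p_end <- profile$end[k]
      } else {
        plat[[length(plat) + 1L]] <- list(start = p_start, end = p_end,
                                          depth = p_depth, samples = cur_set)
        p_start <- profile$start[k]; p_end <- profile$end[k]
        p_depth <- profile$depth[k]; cur_set <- set_k
      }
    }
    plat[[length(plat) + 1L]] <- list(start = p_start, end = p_end,
                                      depth = p_depth, samples = cur_set)
    depths <- vapply(plat, `[[`, numeric(1), "depth")
    n <- length(plat)
    left <- c(-Inf, depths[-n])
    right <- c(depths[-1], -Inf)
    # a locally maximal plateau: no adjacent deeper plateau within the run.
    # equal-depth neighbours (distinct supporter sets) each stand alone.
    is_max <- depths >= left & depths >= right
    for (p in which(is_max)) {
      hs[[length(hs) + 1L]] <- data.frame(
        chrom = chrom, start = plat[[p]]$start, end = plat[[p]]$end,
        length_bp = interval_length(plat[[p]]$start, plat[[p]]$end),
        support = as.integer(plat[[p]]$depth), stringsAsFactors = FALSE)
      hs[[length(hs)]]$samples <- list(plat[[p]]$samples)
    }
  }
  if (!length(hs)) return(as_hotspot_set(empty))
  out <- do.call(rbind, hs)
  out <- out[out$length_bp <= max_length, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  as_hotspot_set(out)
}

as_hotspot_set <- function(df) {
  class(df) <- c("hotspot_set", "data.frame")
  df
}

#' Detect hotspots genome-wide
#'
#' Convenience wrapper chaining [amplified_intervals()],
#' [build_support_profile()] per chromosome and [find_hotspots()].
#'
#' @inheritParams amplified_intervals
#' @inheritParams find_hotspots
#' @return a `hotspot_set` over all chromosomes.
#' @export
detect_hotspots <- function(segments, thresholds = copy_state_thresholds(),
                            min_support = 3, max_length = 2.5e6,
                            merge_gap = 0, include_gain = FALSE) {
  amp <- amplified_intervals(segments, thresholds, merge_gap, include_gain)
  per_chrom <- lapply(sort(unique(amp$chrom)), function(cc) {
    find_hotspots(build_support_profile(amp[amp$chrom == cc, , drop = FALSE], cc),
                  min_support = min_support, max_length = max_length)
  })
  out <- if (length(per_chrom)) do.call(rbind, per_chrom) else find_hotspots(
    build_support_profile(amp[0, , drop = FALSE], "chr0"), min_support, max_length)
  rownames(out) <- NULL
  as_hotspot_set(out)
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("Minimal common regions: %d hotspot(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                       length_bp = x$length_bp, support = x$support)
    if (!is.null(x$genes))
      show$n_genes <- vapply(x$genes, length, integer(1))
    print(utils::head(show, 20))
    if (nrow(x) > 20) cat("... and", nrow(x) - 20, "more\n")
  }
  invisible(x)
}

#' Annotate hotspots with overlapping genes
#'
#' A gene is assigned to a hotspot when their intervals overlap by at least
#' one base. The cohort-level unique gene count (deduplicated across
#' hotspots) is attached as `attr(, "n_unique_genes")`.
#'
#' @param hotspots a `hotspot_set`.
#' @param genes gene table from [read_gene_annotation()].
#' @return the hotspot set with a `genes` list column.
#' @export
annotate_genes <- function(hotspots, genes) {
  gl <- lapply(seq_len(nrow(hotspots)), function(i) {
    hit <- genes$chrom == hotspots$chrom[i] &
      genes$start <= hotspots$end[i] & genes$end >= hotspots$start[i]
    genes$gene_id[hit]
  })
  hotspots$genes <- gl
  attr(hotspots, "n_unique_genes") <- length(unique(unlist(gl)))
  as_hotspot_set(hotspots)
}

#' @rdname annotate_genes
#' @export
n_unique_genes <- function(hotspots) {
  n <- attr(hotspots, "n_unique_genes")
  if (is.null(n)) length(unique(unlist(hotspots$genes))) else n
}

#' Copy state of each sample at a locus
#'
#' For every sample, the length-weighted mean segment log2 ratio over the
#' locus is classified with [call_segment_state()]. Samples with no segment
#' overlapping the locus are omitted.
#'
#' @param segments segment table.
#' @param chrom,start,end locus (1-based inclusive).
#' @param thresholds fold-change thresholds.
#' @return data.frame `sample_id`, `log2_ratio`, `state`.
#' @export
locus_states <- function(segments, chrom, start, end,
                         thresholds = copy_state_thresholds()) {
  sel <- segments$chrom == chrom & segments$start <= end & segments$end >= start
  seg <- segments[sel, , drop = FALSE]
  if (nrow(seg) == 0)
    return(data.frame(sample_id = character(), log2_ratio = numeric(),
                      state = character()))
  w <- pmin(seg$end, end) - pmax(seg$start, start) + 1
  lr <- vapply(split(seq_len(nrow(seg)), seg$sample_id),
               function(idx) sum(seg$log2_ratio[idx] * w[idx]) / sum(w[idx]),
               numeric(1))
  data.frame(sample_id = names(lr), log2_ratio = unname(lr),
             state = as.character(call_segment_state(unname(lr), thresholds)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Associate a hotspot's copy state with a clinical covariate
#'
#' Two Mann-Whitney contrasts against the diploid group are computed (GAIN
#' vs DIPLOID and AMPLIFICATION vs DIPLOID) together with group medians and
#' ranges. The exact null distribution is used when both groups have at
#' most 8 observations and no ties; otherwise the normal approximation with
#' tie correction. An empty group yields a flagged, not-computable row
#' rather than an error.
#'
#' @param states per-sample copy states at the locus (character or factor).
#' @param covariate numeric covariate (e.g. tumor thickness in mm), parallel
#'   to `states`.
#' @param alternative passed to [stats::wilcox.test()]; two-sided default.
#' @return data.frame with one row per contrast: group sizes, `U`,
#'   `p_value`, medians, ranges and a `computable` flag.
#' @export
associate_with_covariate <- function(states, covariate,
                                     alternative = "two.sided") {
  states <- as.character(states)
  stopifnot(length(states) == length(covariate))
  ref <- covariate[states == "DIPLOID"]
  one <- function(grp) {
    x <- covariate[states == grp]
    if (length(x) == 0 || length(ref) == 0) {
      return(data.frame(contrast = paste0(grp, "_vs_DIPLOID"),
                        n_group = length(x), n_diploid = length(ref),
                        U = NA_real_, p_value = NA_real_,
                        median_group = if (length(x)) median(x) else NA_real_,
                        median_diploid = if (length(ref)) median(ref) else NA_real_,
                        range_group = NA_character_, range_diploid = NA_character_,
                        computable = FALSE, stringsAsFactors = FALSE))
    }
    exact <- length(x) <= 8 && length(ref) <= 8 && !anyDuplicated(c(x, ref))
    wt <- suppressWarnings(wilcox.test(x, ref, alternative = alternative,
                                       exact = exact, correct = !exact))
    # fully tied data: zero-variance normal approximation -> no evidence
    if (is.nan(wt$p.value)) wt$p.value <- 1
    data.frame(contrast = paste0(grp, "_vs_DIPLOID"),
               n_group = length(x), n_diploid = length(ref),
               U = unname(wt$statistic), p_value = wt$p.value,
               median_group = median(x), median_diploid = median(ref),
               range_group = paste0(min(x), "-", max(x)),
               range_diploid = paste0(min(ref), "-", max(ref)),
               computable = TRUE, stringsAsFactors = FALSE)
  }
  rbind(one("GAIN"), one("AMPLIFICATION"))
}

#' Cohort-level amplicon summary
#'
#' Descriptive statistics of the per-genome amplification burden: mean
#' number of (merged) amplified intervals per sample, their mean length,
#' and the fraction of samples amplified at an optional locus.
#'
#' @param segments segment table.
#' @param thresholds fold-change thresholds.
#' @param locus optional list/row with `chrom`, `start`, `end`.
#' @return list with `n_samples`, `amplicons_per_genome`, `mean_length_bp`,
#'   and (if `locus` given) `locus_amplified_fraction`.
#' @export
amplicon_summary <- function(segments, thresholds = copy_state_thresholds(),
                             locus = NULL) {
  amp <- amplified_intervals(segments, thresholds)
  n_samples <- length(unique(segments$sample_id))
  out <- list(
    n_samples = n_samples,
    amplicons_per_genome = nrow(amp) / max(1L, n_samples),
    mean_length_bp = if (nrow(amp)) mean(interval_length(amp$start, amp$end)) else NA_real_)
  if (!is.null(locus)) {
    st <- locus_states(segments, locus$chrom, locus$start, locus$end, thresholds)
    out$locus_amplified_fraction <- sum(st$state == "AMPLIFICATION") / max(1L, n_samples)
  }
  out
}
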