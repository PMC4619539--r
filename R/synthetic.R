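#' Specification of a synthetic aCGH cohort
#'
#' Defaults mirror the primary-melanoma discovery cohort the analysis is
#' designed for: 31 genomes on a chr1-sized chromosome, one recurrent
#' amplicon planted at 1q23.1 (chr1:156826196-157106439) amplified in 16%
#' and gained in 10% of samples, a passenger burden of 5.7 amplicons per
#' genome with log-normal lengths of mean 0.47 Mb, and 50 kb probe spacing.
#'
#' @param n_samples number of genomes.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param planted_hotspots data.frame with columns `chrom`, `start`, `end`,
#'   `fraction_amplified`, `fraction_gained`.
#' @param passenger_rate expected passenger amplicons per genome (Poisson).
#' @param passenger_meanlog,passenger_sdlog log-normal length parameters
#'   (bp scale); defaults give mean length 0.47 Mb.
#' @param probe_spacing probe grid step in bp; all breakpoints snap to it.
#' @param guard_margin fold-change margin kept between drawn ratios and the
#'   classification cut points, so noise-free calls match the truth.
#' @param bernoulli if `TRUE`, carrier status is sampled per-sample with
#'   probability `fraction_*`; default `FALSE` uses exact quotas
#'   (`round(fraction * n)`), making small-cohort tests deterministic.
#' @param seed integer seed; one seed drives the whole cohort via a
#'   deterministic fan-out into component child seeds.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 31,
                        chrom_lengths = c(chr1 = 249250621),
                        planted_hotspots = data.frame(
                          chrom = "chr1", start = 156826196, end = 157106439,
                          fraction_amplified = 0.16, fraction_gained = 0.10),
                        passenger_rate = 5.7,
                        passenger_meanlog = log(4.7e5) - 0.8^2 / 2,
                        passenger_sdlog = 0.8,
                        probe_spacing = 50000,
                        guard_margin = 0.05,
                        bernoulli = FALSE,
                        seed = 1L) {
  stopifnot(n_samples >= 1, probe_spacing >= 1, passenger_rate >= 0)
  ph <- planted_hotspots
  if (nrow(ph)) {
    ph$chrom <- normalize_chrom(ph$chrom)
    if (any(!ph$chrom %in% names(chrom_lengths)))
      stop("planted hotspot on a chromosome absent from chrom_lengths")
    if (any(ph$end > chrom_lengths[ph$chrom]) || any(ph$start < 1))
      stop("planted hotspot outside chrom_lengths")
    f <- ph$fraction_amplified + ph$fraction_gained
    if (any(ph$fraction_amplified < 0) || any(ph$fraction_gained < 0) || any(f > 1))
      stop("hotspot fractions must be in [0,1] with amplified + gained <= 1")
  }
  structure(list(n_samples = as.integer(n_samples), chrom_lengths = chrom_lengths,
                 planted_hotspots = ph, passenger_rate = passenger_rate,
                 passenger_meanlog = passenger_meanlog,
                 passenger_sdlog = passenger_sdlog,
                 probe_spacing = probe_spacing, guard_margin = guard_margin,
                 bernoulli = bernoulli, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Thickness model for the synthetic cohort
#'
#' Breslow thickness is log-normal with additive log-scale shifts by copy
#' state at the first planted hotspot. Defaults reproduce the ordering of
#' the printed group medians (2.3 mm diploid, 3.0 mm gained, 4.7 mm
#' amplified).
#'
#' @param base_log_mean,base_log_sd log-mm location and scale of the diploid
#'   group.
#' @param shift_gain,shift_amp additive log-scale shifts for gained and
#'   amplified samples.
#' @return list of class `thickness_model`.
#' @export
thickness_model <- function(base_log_mean = log(2.3), base_log_sd = 0.35,
                            shift_gain = log(3.0 / 2.3),
                            shift_amp = log(4.7 / 2.3)) {
  stopifnot(base_log_sd > 0)
  structure(list(base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 shift_gain = shift_gain, shift_amp = shift_amp),
            class = "thickness_model")
}

#' Survival model for the synthetic cohort
#'
#' Event times are exponential with hazard
#' `baseline_rate * hr_amp^(amplified)` and administrative censoring at
#' `censor_time` months. `hr_amp > 1` puts amplified samples at higher
#' hazard; the defaults used by [simulate_cohort()] place the amplified
#' group at the hazard implied by the printed diploid-vs-amplified hazard
#' ratios (1/0.30 for metastasis-free, 1/0.54 for overall survival).
#'
#' @param baseline_rate events per month in the non-amplified group.
#' @param hr_amp hazard multiplier for amplified samples (> 0).
#' @param censor_time administrative censoring time in months (may be `Inf`).
#' @return list of class `survival_model`.
#' @export
survival_model <- function(baseline_rate = 0.008, hr_amp = 1 / 0.30,
                           censor_time = 120) {
  stopifnot(baseline_rate > 0, hr_amp > 0, censor_time > 0)
  structure(list(baseline_rate = baseline_rate, hr_amp = hr_amp,
                 censor_time = censor_time), class = "survival_model")
}

#' qPCR noise model
#'
#' Generative model for Ct values:
#' `ct = ct_base - log_E(input) + N(0, ct_sd)`, where the input quantity is
#' the true copy ratio for sample wells, 1 for calibrator wells, and the
#' dilution factor for standard-curve wells. Defaults mirror the assay
#' design of two independent experiments of three internal replicates.
#'
#' @param e_target,e_ref PCR efficiencies in (1, 2].
#' @param ct_base_target,ct_base_ref calibrator-input Ct (cycles).
#' @param ct_sd well-level Gaussian noise SD (cycles).
#' @param n_internal_replicates,n_experiments replication design.
#' @param dilution_series dilution factors of the standard curve.
#' @return list of class `qpcr_noise_model`.
#' @export
qpcr_noise_model <- function(e_target = 2, e_ref = 2,
                             ct_base_target = 26, ct_base_ref = 25,
                             ct_sd = 0.15,
                             n_internal_replicates = 3, n_experiments = 2,
                             dilution_series = c(1, 0.1, 0.01, 0.001)) {
  stopifnot(e_target > 1, e_target <= 2, e_ref > 1, e_ref <= 2, ct_sd >= 0,
            n_internal_replicates >= 1, n_experiments >= 1,
            length(dilution_series) >= 3, all(dilution_series > 0))
  structure(list(e_target = e_target, e_ref = e_ref,
                 ct_base_target = ct_base_target, ct_base_ref = ct_base_ref,
                 ct_sd = ct_sd,
                 n_internal_replicates = as.integer(n_internal_replicates),
                 n_experiments = as.integer(n_experiments),
                 dilution_series = dilution_series), class = "qpcr_noise_model")
}

# uniform fold-change bands inside each state's classification interval,
# kept guard_margin away from every cut point so the drawn ratios classify
# back to their generating state with certainty
state_ratio_band <- function(state, thresholds = copy_state_thresholds(),
                             guard = 0.05) {
  switch(state,
         AMPLIFICATION = c(thresholds$amp + guard, 2 * thresholds$amp),
         GAIN = c(thresholds$gain + guard, thresholds$amp - guard),
         DIPLOID = c(thresholds$hemi + guard, thresholds$gain - guard),
         HEMIZYGOUS_DELETION = c(thresholds$homo + guard, thresholds$hemi - guard),
         HOMOZYGOUS_DELETION = c(thresholds$homo / 4, thresholds$homo - guard),
         stop("unknown state ", state))
}

draw_state_ratio <- function(states, thresholds, guard) {
  vapply(states, function(s) {
    b <- state_ratio_band(s, thresholds, guard)
    runif(1, b[1], b[2])
  }, numeric(1))
}

#' Simulate a segmented aCGH cohort with clinical follow-up
#'
#' Generates per-sample segment tables that tile each chromosome without
#' overlap, a clinical table, and a truth sidecar recording every sample's
#' planted copy state and fold change. Carrier samples of a planted hotspot
#' receive an amplified (or gained) segment containing the planted interval,
#' extended by 0-6 probe steps per side; the first carrier's segment equals
#' the planted interval exactly, so the cohort-wide intersection — the
#' minimal common region — is the planted interval itself. Passenger
#' amplicons are placed uniformly away from planted loci. Thickness depends
#' on the copy state at the first planted hotspot; metastasis-free and
#' overall survival times are exponential with the amplified-group hazard
#' multiplied by `hr_amp`.
#'
#' @param spec a [cohort_spec()].
#' @param thickness a [thickness_model()].
#' @param survival a [survival_model()] used for both endpoints, or a list
#'   `list(mfs = , os = )`; the default uses hazard ratios 1/0.30 (MFS) and
#'   1/0.54 (OS) for amplified samples.
#' @param thresholds fold-change thresholds the segment caller will use.
#' @return list with `segments`, `clinical`, `truth` data.frames. `truth`
#'   has one row per sample x planted hotspot (`hotspot_id`, `state`,
#'   `ratio`).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            thickness = thickness_model(),
                            survival = list(mfs = survival_model(hr_amp = 1 / 0.30),
                                            os = survival_model(baseline_rate = 0.005,
                                                                hr_amp = 1 / 0.54)),
                            thresholds = copy_state_thresholds()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(survival, "survival_model")) survival <- list(mfs = survival, os = survival)
  seeds <- fanout_seeds(spec$seed, 4)
  sample_ids <- sprintf("S%02d", seq_len(spec$n_samples))
  ph <- spec$planted_hotspots
  step <- spec$probe_spacing
  guard <- spec$guard_margin

  # -- planted copy states by exact quota (or Bernoulli) ----------------------
  set.seed(seeds[1])
  truth <- list()
  carrier_iv <- list()  # per planted hotspot: carrier intervals
  for (h in seq_len(nrow(ph))) {
    n <- spec$n_samples
    if (spec$bernoulli) {
      u <- runif(n)
      state <- ifelse(u < ph$fraction_amplified[h], "AMPLIFICATION",
               ifelse(u < ph$fraction_amplified[h] + ph$fraction_gained[h],
                      "GAIN", "DIPLOID"))
    } else {
      n_amp <- round(ph$fraction_amplified[h] * n)
      n_gain <- round(ph$fraction_gained[h] * n)
      state <- rep("DIPLOID", n)
      ord <- sample.int(n)
      state[ord[seq_len(n_amp)]] <- "AMPLIFICATION"
      if (n_gain > 0) state[ord[n_amp + seq_len(n_gain)]] <- "GAIN"
    }
    ratio <- draw_state_ratio(state, thresholds, guard)
    truth[[h]] <- data.frame(sample_id = sample_ids,
                             hotspot_id = sprintf("H%02d", h),
                             chrom = ph$chrom[h], start = ph$start[h], end = ph$end[h],
                             state = state, ratio = ratio, stringsAsFactors = FALSE)
    # carrier segment = planted interval extended by 0..6 probes per side;
    # first carrier pinned to the exact planted interval so the cohort
    # intersection equals the truth
    carriers <- which(state != "DIPLOID")
    ext_l <- sample(0:6, length(carriers), replace = TRUE) * step
    ext_r <- sample(0:6, length(carriers), replace = TRUE) * step
    # pin the first amplified carrier (amplification defines the MCR); fall
    # back to the first gained carrier if no sample is amplified
    pin <- which(state[carriers] == "AMPLIFICATION")[1]
    if (is.na(pin) && length(carriers)) pin <- 1L
    if (length(carriers)) { ext_l[pin] <- 0; ext_r[pin] <- 0 }
    carrier_iv[[h]] <- data.frame(
      sample = carriers,
      start = pmax(1, ph$start[h] - ext_l),
      end = pmin(spec$chrom_lengths[ph$chrom[h]], ph$end[h] + ext_r))
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(), hotspot_id = character(),
               chrom = character(), start = numeric(), end = numeric(),
               state = character(), ratio = numeric())

  # -- segments ---------------------------------------------------------------
  set.seed(seeds[2])
  segs <- list()
  for (i in seq_len(spec$n_samples)) {
    for (cc in names(spec$chrom_lengths)) {
      len <- spec$chrom_lengths[[cc]]
      alt <- list()
      for (h in seq_len(nrow(ph))) {
        if (ph$chrom[h] != cc) next
        row <- which(carrier_iv[[h]]$sample == i)
        if (!length(row)) next
        tr <- truth[truth$hotspot_id == sprintf("H%02d", h) &
                      truth$sample_id == sample_ids[i], ]
        alt[[length(alt) + 1L]] <- data.frame(
          start = carrier_iv[[h]]$start[row], end = carrier_iv[[h]]$end[row],
          log2_ratio = log2(tr$ratio))
      }
      # passengers: uniform placement on the probe grid, log-normal length,
      # rejected if they touch a planted locus or an existing alteration
      n_pass <- rpois(1, spec$passenger_rate * len / sum(spec$chrom_lengths))
      placed <- 0; tries <- 0
      while (placed < n_pass && tries < 50 * max(1, n_pass)) {
        tries <- tries + 1
        plen <- max(step, round(rlnorm(1, spec$passenger_meanlog,
                                       spec$passenger_sdlog) / step) * step)
        pstart <- (sample.int(max(1, (len - plen) %/% step), 1) - 1) * step + 1
        pend <- min(len, pstart + plen - 1)
        clash <- FALSE
        for (a in alt) if (pstart <= a$end && pend >= a$start) clash <- TRUE
        if (nrow(ph)) {
          near <- ph$chrom == cc & pstart <= ph$end + step & pend >= ph$start - step
          if (any(near)) clash <- TRUE
        }
        if (clash) next
        ratio <- draw_state_ratio("AMPLIFICATION", thresholds, guard)
        alt[[length(alt) + 1L]] <- data.frame(start = pstart, end = pend,
                                              log2_ratio = log2(ratio))
        placed <- placed + 1
      }
      alt_df <- if (length(alt)) do.call(rbind, alt) else
        data.frame(start = numeric(), end = numeric(), log2_ratio = numeric())
      alt_df <- alt_df[order(alt_df$start), , drop = FALSE]
      # diploid background tiles the complement
      bg <- list()
      cursor <- 1
      for (k in seq_len(nrow(alt_df))) {
        if (alt_df$start[k] > cursor)
          bg[[length(bg) + 1L]] <- data.frame(
            start = cursor, end = alt_df$start[k] - 1,
            log2_ratio = log2(draw_state_ratio("DIPLOID", thresholds, guard)))
        cursor <- alt_df$end[k] + 1
      }
      if (cursor <= len)
        bg[[length(bg) + 1L]] <- data.frame(
          start = cursor, end = len,
          log2_ratio = log2(draw_state_ratio("DIPLOID", thresholds, guard)))
      all_seg <- rbind(alt_df, if (length(bg)) do.call(rbind, bg))
      all_seg <- all_seg[order(all_seg$start), , drop = FALSE]
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample_ids[i], chrom = cc,
        start = all_seg$start, end = all_seg$end,
        log2_ratio = all_seg$log2_ratio, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  segments <- validate_segments(segments)

  # non-carrier samples: the truth fold change at a planted locus is the
  # (diploid) ratio carried by the segment covering it, so the qPCR truth
  # table and the aCGH segments agree at every locus
  for (h in seq_len(nrow(ph))) {
    hid <- sprintf("H%02d", h)
    mid <- floor((ph$start[h] + ph$end[h]) / 2)
    for (i in which(truth$hotspot_id == hid & truth$state == "DIPLOID")) {
      sel <- segments$sample_id == truth$sample_id[i] &
        segments$chrom == ph$chrom[h] &
        segments$start <= mid & segments$end >= mid
      truth$ratio[i] <- 2^segments$log2_ratio[sel][1]
    }
  }

  # -- clinical ---------------------------------------------------------------
  set.seed(seeds[3])
  state1 <- if (nrow(ph)) truth$state[truth$hotspot_id == "H01"] else
    rep("DIPLOID", spec$n_samples)
  shift <- ifelse(state1 == "AMPLIFICATION", thickness$shift_amp,
                  ifelse(state1 == "GAIN", thickness$shift_gain, 0))
  thick <- rlnorm(spec$n_samples, thickness$base_log_mean + shift,
                  thickness$base_log_sd)
  amp <- state1 == "AMPLIFICATION"
  sim_endpoint <- function(model) {
    rate <- model$baseline_rate * ifelse(amp, model$hr_amp, 1)
    t <- stats::rexp(spec$n_samples, rate)
    ev <- as.integer(t <= model$censor_time)
    t <- pmin(t, model$censor_time)
    list(time = t, event = ev)
  }
  mfs <- sim_endpoint(survival$mfs)
  os <- sim_endpoint(survival$os)
  clinical <- data.frame(sample_id = sample_ids,
                         thickness_mm = round(thick, 2),
                         mfs_time = round(mfs$time, 2), mfs_event = mfs$event,
                         os_time = round(os$time, 2), os_event = os$event,
                         stringsAsFactors = FALSE)

  list(segments = segments, clinical = clinical, truth = truth)
}

#' Simulate qPCR Ct records from true copy ratios
#'
#' The generative inverse of the efficiency-corrected quantification:
#' each well's Ct is `ct_base - log_E(input) + N(0, ct_sd)` where the input
#' quantity is the copy ratio (sample wells of the target assay), 1
#' (reference-gene sample wells and calibrator wells) or the dilution
#' factor (standard-curve wells). With `ct_sd = 0` the full calling
#' pipeline returns the planted ratios to machine precision.
#'
#' @param truth_ratios data.frame with columns `sample_id`, `assay`,
#'   `ratio` (> 0): the true fold change of each sample at each target
#'   assay.
#' @param noise a [qpcr_noise_model()].
#' @param reference_assay reference gene assay id (ratio 1 in all samples).
#' @param calibrator_id sample id for calibrator and dilution wells.
#' @param seed integer seed.
#' @return a Ct record data.frame in the [read_ct_table()] schema.
#' @export
simulate_qpcr <- function(truth_ratios, noise = qpcr_noise_model(),
                          reference_assay = "LAMA1",
                          calibrator_id = "CAL_POOL", seed = 1L) {
  stopifnot(all(truth_ratios$ratio > 0))
  set.seed(as.integer(seed))
  assays <- unique(truth_ratios$assay)
  rows <- list()
  emit <- function(sample_id, assay, role, dil, q, base, e) {
    for (ex in seq_len(noise$n_experiments))
      for (rp in seq_len(noise$n_internal_replicates)) {
        ct <- base - log(q, base = e) + rnorm(1, 0, noise$ct_sd)
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sample_id, assay = assay, role = role,
          dilution_factor = dil, experiment_id = paste0("exp", ex),
          replicate_id = paste0("r", rp), ct = ct, stringsAsFactors = FALSE)
      }
  }
  for (a in c(assays, reference_assay)) {
    is_ref <- a == reference_assay
    e <- if (is_ref) noise$e_ref else noise$e_target
    base <- if (is_ref) noise$ct_base_ref else noise$ct_base_target
    for (d in noise$dilution_series)
      emit(calibrator_id, a, "dilution", d, d, base, e)
    emit(calibrator_id, a, "calibrator", NA_real_, 1, base, e)
    if (is_ref) {
      for (sid in unique(truth_ratios$sample_id))
        emit(sid, a, "sample", NA_real_, 1, base, e)
    } else {
      tr <- truth_ratios[truth_ratios$assay == a, , drop = FALSE]
      for (k in seq_len(nrow(tr)))
        emit(tr$sample_id[k], a, "sample", NA_real_, tr$ratio[k], base, e)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_ct(out)
}

#' Synthetic gene annotation around planted hotspots
#'
#' Emits a small gene model set: `genes_per_hotspot` genes tiled across each
#' planted hotspot (so annotation steps have hits) plus `n_background`
#' genes placed uniformly elsewhere.
#'
#' @param spec a [cohort_spec()].
#' @param genes_per_hotspot,n_background counts of planted and background genes.
#' @param seed integer seed.
#' @return gene table in the [read_gene_annotation()] schema.
#' @export
simulate_genes <- function(spec = cohort_spec(), genes_per_hotspot = 8,
                           n_background = 50, seed = 1L) {
  set.seed(as.integer(seed))
  ph <- spec$planted_hotspots
  g <- list()
  for (h in seq_len(nrow(ph))) {
    w <- (ph$end[h] - ph$start[h] + 1) / genes_per_hotspot
    s <- round(ph$start[h] + (seq_len(genes_per_hotspot) - 1) * w)
    g[[h]] <- data.frame(gene_id = sprintf("HS%02d_G%02d", h, seq_len(genes_per_hotspot)),
                         chrom = ph$chrom[h], start = s,
                         end = pmin(ph$end[h], round(s + 0.8 * w)),
                         strand = sample(c("+", "-"), genes_per_hotspot, TRUE),
                         stringsAsFactors = FALSE)
  }
  cc <- sample(names(spec$chrom_lengths), n_background, replace = TRUE,
               prob = spec$chrom_lengths / sum(spec$chrom_lengths))
  s <- vapply(cc, function(c1) sample.int(spec$chrom_lengths[[c1]] - 100000, 1),
              numeric(1))
  g[[length(g) + 1L]] <- data.frame(gene_id = sprintf("BG_G%03d", seq_len(n_background)),
                                    chrom = cc, start = s, end = s + 50000,
                                    strand = sample(c("+", "-"), n_background, TRUE),
                                    stringsAsFactors = FALSE)
  out <- do.call(rbind, g)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
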