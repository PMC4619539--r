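#' Copy-state thresholds on the fold-change scale
#'
#' Fold change over the diploid calibrator is cut into five states:
#' homozygous deletion below 0.5, hemizygous deletion from 0.5 to 0.75,
#' diploid strictly between 0.75 and 1.25, single-copy gain from 1.25 to
#' 1.75, and amplification strictly above 1.75. The exact boundary values
#' belong to the non-diploid state (deletions and gain include their outer
#' bound; amplification is strictly > `amp`).
#'
#' @param homo,hemi,gain,amp the four cut points (fold change).
#' @return a named list of ordered thresholds.
#' @export
copy_state_thresholds <- function(homo = 0.5, hemi = 0.75, gain = 1.25, amp = 1.75) {
  th <- list(homo = homo, hemi = hemi, gain = gain, amp = amp)
  if (!(0 < homo && homo < hemi && hemi < gain && gain < amp))
    stop("thresholds must satisfy 0 < homo < hemi < gain < amp")
  if (!(hemi < 1 && gain > 1)) stop("the diploid band must contain fold change 1")
  th
}

#' The five copy states, ordered
#' @return character vector of state labels from deepest loss to amplification.
#' @export
copy_states <- function() {
  c("HOMOZYGOUS_DELETION", "HEMIZYGOUS_DELETION", "DIPLOID", "GAIN", "AMPLIFICATION")
}

#' Classify a fold change into a copy state
#'
#' @param ratio positive fold change(s) over the diploid calibrator.
#' @param thresholds see [copy_state_thresholds()].
#' @return ordered factor of copy states, levels [copy_states()].
#' @export
#' @examples
#' classify_fold_change(c(0.4, 0.6, 1.0, 1.5, 1.8))
classify_fold_change <- function(ratio, thresholds = copy_state_thresholds()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) stop("ratio must be positive and finite")
  st <- ifelse(ratio < thresholds$homo, "HOMOZYGOUS_DELETION",
        ifelse(ratio <= thresholds$hemi, "HEMIZYGOUS_DELETION",
        ifelse(ratio < thresholds$gain, "DIPLOID",
        ifelse(ratio <= thresholds$amp, "GAIN", "AMPLIFICATION"))))
  factor(st, levels = copy_states(), ordered = TRUE)
}

#' Classify a segment mean log2 ratio
#'
#' Applies [classify_fold_change()] to `2^log2_ratio`. Array and qPCR
#' thresholds are independently configurable; the defaults are the same
#' fold-change cut points.
#'
#' @param log2_ratio segment mean log2 ratio(s).
#' @param thresholds see [copy_state_thresholds()].
#' @return ordered factor of copy states.
#' @export
call_segment_state <- function(log2_ratio, thresholds = copy_state_thresholds()) {
  classify_fold_change(2^log2_ratio, thresholds)
}

#' Aggregate replicate Ct values
#'
#' Wells are averaged within each independent experiment (internal
#' replicates) and the experiment means are then averaged; the reported SD
#' is the standard deviation of the experiment means. This matches the
#' design of two independent runs of three internal replicates each.
#' Experiments whose internal-replicate SD exceeds `qc_cutoff` cycles are
#' flagged, not dropped.
#'
#' @param ct numeric Ct values (cycles) for one sample x assay.
#' @param experiment_id parallel vector of experiment labels.
#' @param qc_cutoff replicate-SD QC threshold in cycles.
#' @return list with `mean`, `sd` (NA for a single experiment),
#'   `n_experiments`, `n_wells`, `flags` (character).
#' @export
aggregate_ct <- function(ct, experiment_id = rep("e1", length(ct)), qc_cutoff = 0.5) {
  if (length(ct) == 0) stop("no Ct values to aggregate")
  if (length(experiment_id) != length(ct)) stop("experiment_id length mismatch")
  per_exp <- split(ct, experiment_id)
  means <- vapply(per_exp, mean, numeric(1))
  reps_sd <- vapply(per_exp, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                    numeric(1))
  flags <- character(0)
  if (length(ct) == 1) flags <- c(flags, "single_well")
  if (any(!is.na(reps_sd) & reps_sd > qc_cutoff)) flags <- c(flags, "high_replicate_sd")
  list(mean = mean(means),
       sd = if (length(means) > 1) stats::sd(means) else NA_real_,
       n_experiments = length(means),
       n_wells = length(ct),
       flags = flags)
}

#' Fit a standard curve and estimate PCR efficiency
#'
#' Least-squares regression of mean Ct against log10(dilution factor) over a
#' calibrator dilution series. The efficiency is \eqn{E = 10^{-1/slope}};
#' a perfect doubling assay has slope \eqn{-\log_2 10 \approx -3.3219} and
#' E = 2. Apparent efficiencies slightly above 2 (up to 2.1) are flagged as
#' super-efficient but kept; beyond that the fit is rejected.
#'
#' @param ct Ct records for dilution wells: either a `data.frame` with
#'   columns `dilution_factor` and `ct`, or a numeric Ct vector with
#'   `dilution_factor` supplied separately.
#' @param dilution_factor dilution factors when `ct` is a numeric vector.
#' @param assay assay label carried into the result.
#' @return an object of class `standard_curve` with fields `assay`, `slope`
#'   (cycles per log10 dilution), `intercept`, `efficiency`, `r_squared`,
#'   `n_levels`, `flags`.
#' @export
#' @examples
#' fit_standard_curve(c(20, 23.3219, 26.6439), c(1, 0.1, 0.01))
fit_standard_curve <- function(ct, dilution_factor = NULL, assay = NA_character_) {
  if (is.data.frame(ct)) {
    dilution_factor <- ct$dilution_factor
    ct <- ct$ct
  }
  if (any(dilution_factor <= 0)) stop("dilution factors must be positive")
  mean_ct <- tapply(ct, dilution_factor, mean)
  lv <- as.numeric(names(mean_ct))
  if (length(lv) < 3) stop("standard curve needs >= 3 distinct dilution factors")
  fit <- lm(as.numeric(mean_ct) ~ log10(lv))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard-curve slope must be negative (Ct increases with dilution)")
  eff <- 10^(-1 / slope)
  flags <- character(0)
  if (eff > 2.1) stop("implausible PCR efficiency ", format(eff), " (> 2.1)")
  if (eff > 2) flags <- c(flags, "super_efficient")
  if (eff <= 1) stop("PCR efficiency must exceed 1")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noise-free series fit exactly
  structure(list(assay = assay, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = eff, r_squared = r2,
                 n_levels = length(lv), flags = flags),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s: slope %.4f cycles/log10, E = %.4f, R2 = %s (%d dilution levels)\n",
              if (is.na(x$assay)) "" else paste0(" [", x$assay, "]"),
              x$slope, x$efficiency,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n_levels))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Efficiency-corrected relative copy-number ratio (Pfaffl)
#'
#' \deqn{ratio = E_t^{Ct_{cal,t} - Ct_{s,t}} / E_r^{Ct_{cal,r} - Ct_{s,r}}}
#' where t is the target assay, r the reference gene, s the sample and cal
#' the diploid calibrator. With both efficiencies at 2 this reduces to the
#' ddCt ratio \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct_sample_target,ct_cal_target target-assay Ct of sample and calibrator.
#' @param ct_sample_ref,ct_cal_ref reference-assay Ct of sample and calibrator.
#' @param e_target,e_ref PCR efficiencies (> 1).
#' @return fold change(s) over the calibrator.
#' @export
efficiency_corrected_ratio <- function(ct_sample_target, ct_cal_target,
                                       ct_sample_ref, ct_cal_ref,
                                       e_target, e_ref) {
  if (any(e_target <= 1) || any(e_ref <= 1)) stop("efficiencies must exceed 1")
  e_target^(ct_cal_target - ct_sample_target) / e_ref^(ct_cal_ref - ct_sample_ref)
}

#' ddCt relative quantification
#'
#' The classical \eqn{2^{-\Delta\Delta Ct}} ratio; identical to
#' [efficiency_corrected_ratio()] with both efficiencies fixed at 2.
#'
#' @inheritParams efficiency_corrected_ratio
#' @return fold change(s) over the calibrator.
#' @export
ddct_ratio <- function(ct_sample_target, ct_cal_target,
                       ct_sample_ref, ct_cal_ref) {
  efficiency_corrected_ratio(ct_sample_target, ct_cal_target,
                             ct_sample_ref, ct_cal_ref, 2, 2)
}

#' Call copy number from a Ct table
#'
#' Full qPCR quantification: per-assay standard curves are fitted from the
#' dilution wells (skipped under `method = "ddct"`, which fixes E = 2),
#' sample and calibrator Cts are aggregated with [aggregate_ct()], the
#' efficiency-corrected ratio over the reference gene is computed per
#' sample, and fold changes are classified with [classify_fold_change()].
#'
#' @param ct validated Ct records (see [read_ct_table()]).
#' @param reference_assay reference gene assay id (default `"LAMA1"`, a
#'   locus chosen for its copy-number stability).
#' @param calibrator_id sample id of the diploid calibrator wells.
#' @param target_assays assays to call; default: all non-reference assays.
#' @param method `"pfaffl"` (standard-curve efficiencies) or `"ddct"` (E = 2).
#' @param combine `"aggregated_ct"` (one ratio from experiment-aggregated
#'   Cts; default) or `"mean_of_ratios"` (per-experiment ratios averaged).
#' @param thresholds see [copy_state_thresholds()].
#' @param qc_cutoff replicate-SD flag threshold in cycles.
#' @return a `fold_change_table` data.frame with columns `sample_id`,
#'   `assay`, `ratio`, `log2_ratio`, `state`, `ct_sd`, `qc_flags`; fitted
#'   standard curves in `attr(, "standard_curves")`.
#' @export
qpcr_copy_calls <- function(ct, reference_assay = "LAMA1",
                            calibrator_id = "CAL_POOL",
                            target_assays = NULL,
                            method = c("pfaffl", "ddct"),
                            combine = c("aggregated_ct", "mean_of_ratios"),
                            thresholds = copy_state_thresholds(),
                            qc_cutoff = 0.5) {
  method <- match.arg(method)
  combine <- match.arg(combine)
  ct <- validate_ct(ct)
  assays <- unique(ct$assay)
  if (!reference_assay %in% assays)
    stop("reference assay '", reference_assay, "' absent from Ct table")
  if (is.null(target_assays)) target_assays <- setdiff(assays, reference_assay)

  curves <- list()
  eff <- setNames(rep(2, length(assays)), assays)
  if (method == "pfaffl") {
    for (a in assays) {
      dil <- ct[ct$assay == a & ct$role == "dilution", , drop = FALSE]
      if (nrow(dil) == 0)
        stop("no dilution series for assay '", a, "' (required for pfaffl method)")
      curves[[a]] <- fit_standard_curve(dil, assay = a)
      eff[a] <- curves[[a]]$efficiency
      mc_log("debug", sprintf("assay %s: E = %.4f", a, eff[a]))
    }
  }

  cal <- ct[ct$role == "calibrator" & ct$sample_id == calibrator_id, , drop = FALSE]
  if (nrow(cal) == 0) stop("no calibrator wells for '", calibrator_id, "'")
  samp <- ct[ct$role == "sample", , drop = FALSE]
  sample_ids <- unique(samp$sample_id)

  agg <- function(rows) aggregate_ct(rows$ct, rows$experiment_id, qc_cutoff)
  pick <- function(df, sid, a) df[df$sample_id == sid & df$assay == a, , drop = FALSE]

  out <- list()
  for (a in target_assays) {
    cal_t <- pick(cal, calibrator_id, a)
    cal_r <- pick(cal, calibrator_id, reference_assay)
    if (nrow(cal_t) == 0 || nrow(cal_r) == 0)
      stop("calibrator wells missing for assay '", a, "' or reference")
    for (sid in sample_ids) {
      st <- pick(samp, sid, a)
      sr <- pick(samp, sid, reference_assay)
      if (nrow(st) == 0 || nrow(sr) == 0) next
      if (combine == "aggregated_ct") {
        at <- agg(st); ar <- agg(sr); ct_t <- agg(cal_t); ct_r <- agg(cal_r)
        ratio <- efficiency_corrected_ratio(at$mean, ct_t$mean, ar$mean, ct_r$mean,
                                            eff[a], eff[reference_assay])
        sdv <- at$sd
        flags <- unique(c(at$flags, ar$flags, ct_t$flags, ct_r$flags))
      } else {
        exps <- intersect(unique(st$experiment_id), unique(sr$experiment_id))
        per_exp <- vapply(exps, function(e) {
          # use calibrator wells from the same experiment when present
          ct_cal_t <- cal_t$ct[cal_t$experiment_id == e]
          if (!length(ct_cal_t)) ct_cal_t <- cal_t$ct
          ct_cal_r <- cal_r$ct[cal_r$experiment_id == e]
          if (!length(ct_cal_r)) ct_cal_r <- cal_r$ct
          efficiency_corrected_ratio(mean(st$ct[st$experiment_id == e]),
                                     mean(ct_cal_t),
                                     mean(sr$ct[sr$experiment_id == e]),
                                     mean(ct_cal_r),
                                     eff[a], eff[reference_assay])
        }, numeric(1))
        ratio <- mean(per_exp)
        sdv <- if (length(per_exp) > 1) stats::sd(per_exp) else NA_real_
        flags <- character(0)
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, assay = a, ratio = ratio,
        log2_ratio = log2(ratio),
        state = as.character(classify_fold_change(ratio, thresholds)),
        ct_sd = sdv,
        qc_flags = paste(flags, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$assay, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "standard_curves") <- curves
  class(res) <- c("fold_change_table", class(res))
  res
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("qPCR fold changes: %d calls, %d assay(s), %d sample(s)\n",
              nrow(x), length(unique(x$assay)), length(unique(x$sample_id))))
  tab <- table(x$assay, factor(x$state, levels = copy_states()))
  print(tab[, colSums(tab) > 0, drop = FALSE])
  invisible(x)
}
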