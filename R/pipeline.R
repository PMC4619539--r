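#' Pipeline configuration
#'
#' Reads a YAML configuration (or takes a list) and merges it over the
#' package defaults. Every analysis threshold is surfaced here — nothing is
#' hard-coded in the stage commands.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return validated configuration list of class `pipeline_config`, with the
#'   configuration hash in `attr(, "hash")`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    inputs = list(segments = NULL, annotation = NULL, ct = NULL, clinical = NULL),
    thresholds = list(homo = 0.5, hemi = 0.75, gain = 1.25, amp = 1.75),
    hotspot = list(min_support = 3, max_length = 2.5e6, merge_gap = 0,
                   include_gain = FALSE),
    qpcr = list(reference_assay = "LAMA1", calibrator_id = "CAL_POOL",
                method = "pfaffl", combine = "aggregated_ct", qc_cutoff = 0.5),
    concordance = list(epsilon = 0,
                       locus = list(chrom = "chr1", start = 156826196,
                                    end = 157106439),
                       assay = NULL),
    survival = list(groups = c("AMPLIFICATION", "DIPLOID"),
                    method = "mantel-haenszel"),
    simulate = list(n_samples = 31, seed_offset = 0),
    seed = 1L,
    out_dir = ".")
  cfg <- modify_list_deep(defaults, config)
  th <- cfg$thresholds
  do.call(copy_state_thresholds, th)  # validates ordering
  if (cfg$hotspot$min_support < 1) stop("min_support must be >= 1")
  structure(cfg, hash = config_hash(cfg), class = c("pipeline_config", "list"))
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

cfg_thresholds <- function(cfg) do.call(copy_state_thresholds, cfg$thresholds)

#' Run the hotspot stage
#'
#' Reads the segment table (plus optional gene annotation and clinical
#' table), detects minimal common regions of amplification, annotates
#' genes, associates the copy state at each hotspot with tumor thickness,
#' and writes `hotspots.tsv` (and `hotspot_association.tsv` when clinical
#' data are available) into the output directory.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @param out_dir output directory; defaults to the config's `out_dir`.
#' @return invisibly, a list with the hotspot set and association table.
#' @export
cmd_hotspots <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg_thresholds(cfg)
  if (is.null(cfg$inputs$segments)) stop("config: inputs.segments is required")
  segments <- read_segments(cfg$inputs$segments)
  mc_log("info", "read ", nrow(segments), " segments / ",
         length(unique(segments$sample_id)), " samples")
  hs <- detect_hotspots(segments, thresholds = th,
                        min_support = cfg$hotspot$min_support,
                        max_length = cfg$hotspot$max_length,
                        merge_gap = cfg$hotspot$merge_gap,
                        include_gain = cfg$hotspot$include_gain)
  mc_log("info", nrow(hs), " hotspot(s) at min_support=", cfg$hotspot$min_support)
  if (!is.null(cfg$inputs$annotation)) {
    genes <- read_gene_annotation(cfg$inputs$annotation)
    hs <- annotate_genes(hs, genes)
    mc_log("info", n_unique_genes(hs), " unique genes across hotspots")
  }
  params <- list(min_support = cfg$hotspot$min_support,
                 max_length = cfg$hotspot$max_length,
                 merge_gap = cfg$hotspot$merge_gap,
                 amp_threshold = th$amp)
  write_hotspot_report(hs, file.path(out_dir, "hotspots.tsv"),
                       params = params, hash = attr(cfg, "hash"))
  assoc <- NULL
  if (!is.null(cfg$inputs$clinical) && nrow(hs)) {
    clinical <- read_clinical_table(cfg$inputs$clinical)
    rows <- lapply(seq_len(nrow(hs)), function(i) {
      st <- locus_states(segments, hs$chrom[i], hs$start[i], hs$end[i], th)
      m <- merge(st, clinical, by = "sample_id")
      if (!nrow(m)) return(NULL)
      a <- associate_with_covariate(m$state, m$thickness_mm)
      a$hotspot <- sprintf("%s:%d-%d", hs$chrom[i], hs$start[i], hs$end[i])
      a
    })
    assoc <- do.call(rbind, rows)
    if (!is.null(assoc)) {
      # rank hotspots by their amplification-contrast p value
      is_amp <- assoc$contrast == "AMPLIFICATION_vs_DIPLOID"
      amp_p <- setNames(assoc$p_value[is_amp], assoc$hotspot[is_amp])
      key <- amp_p[assoc$hotspot]
      key[is.na(key)] <- Inf
      assoc <- assoc[order(key, assoc$hotspot, assoc$contrast), , drop = FALSE]
      write_tsv_report(assoc, file.path(out_dir, "hotspot_association.tsv"),
                       "hotspot_association", params = params,
                       hash = attr(cfg, "hash"))
    }
  }
  invisible(list(hotspots = hs, association = assoc))
}

#' Run the qPCR copy-calling stage
#'
#' Reads the Ct table, fits per-assay standard curves, computes
#' efficiency-corrected fold changes over the calibrator and writes
#' `fold_changes.tsv`.
#'
#' @inheritParams cmd_hotspots
#' @return invisibly, the `fold_change_table`.
#' @export
cmd_qpcr_call <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$inputs$ct)) stop("config: inputs.ct is required")
  ct <- read_ct_table(cfg$inputs$ct)
  fc <- qpcr_copy_calls(ct,
                        reference_assay = cfg$qpcr$reference_assay,
                        calibrator_id = cfg$qpcr$calibrator_id,
                        method = cfg$qpcr$method,
                        combine = cfg$qpcr$combine,
                        thresholds = cfg_thresholds(cfg),
                        qc_cutoff = cfg$qpcr$qc_cutoff)
  for (cv in attr(fc, "standard_curves"))
    mc_log("info", sprintf("assay %s: E = %.4f (R2 = %.4f)",
                           cv$assay, cv$efficiency, cv$r_squared))
  write_tsv_report(fc, file.path(out_dir, "fold_changes.tsv"), "fold_changes",
                   params = cfg$qpcr, hash = attr(cfg, "hash"))
  invisible(fc)
}

#' Run the cross-platform concordance stage
#'
#' Compares qPCR log2 fold changes with the aCGH mean log2 ratio over the
#' configured locus for the shared samples; writes per-sample signs and a
#' summary (consistent count, Pearson r and p) to `concordance.tsv`.
#'
#' @inheritParams cmd_hotspots
#' @return invisibly, a list with the pair table, concordance and Pearson
#'   results.
#' @export
cmd_concord <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$inputs$ct) || is.null(cfg$inputs$segments))
    stop("config: inputs.ct and inputs.segments are required")
  fc <- qpcr_copy_calls(read_ct_table(cfg$inputs$ct),
                        reference_assay = cfg$qpcr$reference_assay,
                        calibrator_id = cfg$qpcr$calibrator_id,
                        method = cfg$qpcr$method, combine = cfg$qpcr$combine,
                        thresholds = cfg_thresholds(cfg),
                        qc_cutoff = cfg$qpcr$qc_cutoff)
  assay <- cfg$concordance$assay %||% unique(fc$assay)[1]
  fc <- fc[fc$assay == assay, , drop = FALSE]
  loc <- cfg$concordance$locus
  segments <- read_segments(cfg$inputs$segments)
  acgh <- locus_states(segments, normalize_chrom(loc$chrom), loc$start, loc$end,
                       cfg_thresholds(cfg))
  pairs <- merge(fc[, c("sample_id", "log2_ratio")],
                 acgh[, c("sample_id", "log2_ratio")],
                 by = "sample_id", suffixes = c("_qpcr", "_acgh"))
  if (nrow(pairs) < 3) stop("fewer than 3 shared samples for concordance")
  conc <- direction_concordance(pairs$log2_ratio_qpcr, pairs$log2_ratio_acgh,
                                cfg$concordance$epsilon)
  pe <- pearson_cor(pairs$log2_ratio_qpcr, pairs$log2_ratio_acgh)
  mc_log("info", sprintf("concordance: %d/%d consistent; Pearson r = %.3f (p = %.3g)",
                         conc$n_consistent, conc$n, pe$r, pe$p_value))
  pairs$consistent <- conc$consistent
  write_tsv_report(pairs, file.path(out_dir, "concordance.tsv"), "concordance",
                   params = list(assay = assay, epsilon = cfg$concordance$epsilon,
                                 locus = sprintf("%s:%d-%d", loc$chrom,
                                                 loc$start, loc$end),
                                 n_consistent = conc$n_consistent, n = conc$n,
                                 pearson_r = pe$r, pearson_p = pe$p_value),
                   hash = attr(cfg, "hash"))
  invisible(list(pairs = pairs, concordance = conc, pearson = pe))
}

#' Run the survival stage
#'
#' Calls copy states from the Ct table, joins the clinical table and
#' compares the configured copy-state groups for both endpoints
#' (metastasis-free and overall survival); writes `survival.tsv`.
#'
#' @inheritParams cmd_hotspots
#' @return invisibly, a list of `survival_comparison` objects (`mfs`, `os`).
#' @export
cmd_survival <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$inputs$ct) || is.null(cfg$inputs$clinical))
    stop("config: inputs.ct and inputs.clinical are required")
  fc <- qpcr_copy_calls(read_ct_table(cfg$inputs$ct),
                        reference_assay = cfg$qpcr$reference_assay,
                        calibrator_id = cfg$qpcr$calibrator_id,
                        method = cfg$qpcr$method, combine = cfg$qpcr$combine,
                        thresholds = cfg_thresholds(cfg),
                        qc_cutoff = cfg$qpcr$qc_cutoff)
  assay <- cfg$concordance$assay %||% unique(fc$assay)[1]
  fc <- fc[fc$assay == assay, , drop = FALSE]
  clinical <- read_clinical_table(cfg$inputs$clinical)
  res <- lapply(c(mfs = "mfs", os = "os"), function(ep)
    survival_by_state(fc, clinical, endpoint = ep,
                      groups = cfg$survival$groups,
                      method = cfg$survival$method))
  rows <- do.call(rbind, lapply(names(res), function(ep) {
    x <- res[[ep]]
    data.frame(endpoint = ep, group1 = x$labels[1], group2 = x$labels[2],
               n1 = x$n[1], n2 = x$n[2],
               events1 = x$observed[1], events2 = x$observed[2],
               logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p,
               hr = x$hr, hr_ci_low = x$hr_ci95[1], hr_ci_high = x$hr_ci95[2],
               stringsAsFactors = FALSE)
  }))
  for (ep in names(res))
    mc_log("info", sprintf("%s: HR = %.3f (%.3f-%.3f), log-rank p = %.3g", ep,
                           res[[ep]]$hr, res[[ep]]$hr_ci95[1],
                           res[[ep]]$hr_ci95[2], res[[ep]]$logrank_p))
  write_tsv_report(rows, file.path(out_dir, "survival.tsv"), "survival",
                   params = list(assay = assay,
                                 groups = paste(cfg$survival$groups, collapse = "_vs_"),
                                 method = cfg$survival$method),
                   hash = attr(cfg, "hash"))
  invisible(res)
}

#' Generate a full synthetic input set
#'
#' Simulates a cohort at the configured size and seed and writes
#' `segments.tsv`, `clinical.tsv`, `ct.tsv`, `genes.bed` and the
#' `truth.tsv` sidecar into the output directory, all in the io-module
#' schemas, so the other stages can be run on them directly.
#'
#' @inheritParams cmd_hotspots
#' @return invisibly, the simulated cohort plus the file paths.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed + cfg$simulate$seed_offset
  spec <- cohort_spec(n_samples = cfg$simulate$n_samples, seed = seed)
  co <- simulate_cohort(spec, thresholds = cfg_thresholds(cfg))
  tr <- co$truth[co$truth$hotspot_id == "H01", , drop = FALSE]
  truth_ratios <- data.frame(sample_id = tr$sample_id, assay = "NTRK1",
                             ratio = tr$ratio, stringsAsFactors = FALSE)
  ct <- simulate_qpcr(truth_ratios,
                      reference_assay = cfg$qpcr$reference_assay,
                      calibrator_id = cfg$qpcr$calibrator_id,
                      seed = seed + 1)
  genes <- simulate_genes(spec, seed = seed + 2)
  h <- attr(cfg, "hash")
  paths <- list(
    segments = write_segments(co$segments, file.path(out_dir, "segments.tsv"),
                              params = list(seed = seed), hash = h),
    clinical = write_clinical_table(co$clinical, file.path(out_dir, "clinical.tsv"),
                                    params = list(seed = seed), hash = h),
    ct = write_ct_table(ct, file.path(out_dir, "ct.tsv"),
                        params = list(seed = seed + 1), hash = h),
    truth = write_tsv_report(co$truth, file.path(out_dir, "truth.tsv"), "truth",
                             params = list(seed = seed), hash = h),
    genes = file.path(out_dir, "genes.bed"))
  # BED is 0-based half-open: convert from the internal 1-based inclusive form
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1, end = genes$end,
                    name = genes$gene_id, score = 0, strand = genes$strand)
  write.table(bed, paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  mc_log("info", "simulated cohort written to ", out_dir)
  invisible(c(co, list(ct = ct, genes = genes, paths = paths)))
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `hotspots`, `qpcr-call`, `concord` and
#' `survival` subcommands; each accepts `--config <yaml>`, `--out <dir>`,
#' `--seed <int>` and `--log-level <quiet|info|debug>`. Used by the
#' `inst/exec/mcramp` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: mcramp <simulate|hotspots|qpcr-call|concord|survival>",
        "[--config FILE] [--out DIR] [--seed INT] [--log-level LEVEL]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- list(config = NULL, out = NULL, seed = NULL, log_level = "info")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  old <- options(mcramp.log_level = opt$log_level)
  on.exit(options(old))
  cfg <- if (is.null(opt$config)) list() else yaml::read_yaml(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  fun <- switch(sub,
                simulate = cmd_simulate,
                hotspots = cmd_hotspots,
                `qpcr-call` = cmd_qpcr_call,
                concord = cmd_concord,
                survival = cmd_survival,
                stop("unknown subcommand: ", sub))
  fun(cfg)
  invisible(0L)
}
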