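#' Read a segmented copy-number table
#'
#' Reads the tab-delimited per-sample segment table produced by upstream
#' aCGH segmentation (columns `sample_id`, `chrom`, `start`, `end`,
#' `log2_ratio`; `log2_ratio` is the segment mean test/reference log2
#' ratio). Coordinates are interpreted as 1-based inclusive. Records are
#' validated and returned sorted by (sample, chromosome, start); overlapping
#' segments of one sample on one chromosome are an error, not silently
#' merged.
#'
#' @param path path to a TSV file with a header row; lines starting with
#'   `#` are ignored.
#' @return a `data.frame` of validated segment records.
#' @export
read_segments <- function(path) {
  df <- read_delimited(path, sep = "\t")
  need_columns(df, c("sample_id", "chrom", "start", "end", "log2_ratio"), path)
  if (nrow(df) == 0) return(empty_segments())
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- parse_coord(df$start, "start", path)
  df$end <- parse_coord(df$end, "end", path)
  df$log2_ratio <- parse_num(df$log2_ratio, "log2_ratio", path)
  validate_segments(df)
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(), log2_ratio = numeric(),
             stringsAsFactors = FALSE)
}

validate_segments <- function(df) {
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("segment row ", bad[1], ": start >= end (1-based inclusive, start < end required)")
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  by_sc <- split(seq_len(nrow(df)), list(df$sample_id, df$chrom), drop = TRUE)
  for (idx in by_sc) {
    if (length(idx) < 2) next
    s <- df$start[idx]; e <- df$end[idx]
    if (any(s[-1] <= e[-length(e)]))
      stop("overlapping segments for sample ", df$sample_id[idx[1]],
           " on ", df$chrom[idx[1]])
  }
  df
}

#' Read gene annotation from BED or GFF
#'
#' BED input is 0-based half-open and GFF/GTF 1-based inclusive; both are
#' converted to the package-wide 1-based inclusive convention on read, so a
#' BED line `chr1 100 200 geneA` becomes the interval 101..200. Parsing is
#' delegated to [rtracklayer::import()].
#'
#' @param path path with a recognized extension (`.bed`, `.gff`, `.gff3`,
#'   `.gtf`).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext,
                bed = "BED",
                gff = , gff3 = , gtf = "GFF",
                stop("unknown annotation extension: .", ext))
  gr <- rtracklayer::import(path, format = fmt)
  if (any(GenomicRanges::width(gr) < 1))
    stop("annotation contains an empty interval (end <= start in BED terms)")
  md <- as.data.frame(gr)
  id <- md$name %||% md$gene_id %||% md$ID %||% md$Name
  if (is.null(id)) id <- paste0("feature_", seq_along(gr))
  id <- as.character(id)
  id[is.na(id) | !nzchar(id)] <- paste0("feature_", which(is.na(id) | !nzchar(id)))
  out <- data.frame(gene_id = id,
                    chrom = normalize_chrom(md$seqnames),
                    start = as.numeric(md$start),
                    end = as.numeric(md$end),
                    strand = as.character(md$strand),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "."
  if (any(out$start >= out$end)) stop("gene with start >= end after conversion")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a qPCR cycle-threshold table
#'
#' Long-format Ct table covering sample, calibrator and dilution-series
#' wells (columns `sample_id`, `assay`, `role`, `dilution_factor`,
#' `experiment_id`, `replicate_id`, `ct`). `role` must be one of
#' `sample`, `calibrator`, `dilution`; `dilution_factor` must be present
#' exactly for dilution wells. Duplicated wells (same sample, assay, role,
#' dilution, experiment and replicate) are an error rather than being
#' silently averaged.
#'
#' @param path path to a TSV (`.tsv`/`.txt`) or CSV (`.csv`) file.
#' @return `data.frame` of validated Ct records.
#' @export
read_ct_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- read_delimited(path, sep = sep)
  cols <- c("sample_id", "assay", "role", "dilution_factor",
            "experiment_id", "replicate_id", "ct")
  need_columns(df, cols, path)
  if (nrow(df) == 0) return(df[, cols])
  for (ch in c("sample_id", "assay", "role", "experiment_id", "replicate_id"))
    df[[ch]] <- as.character(df[[ch]])
  df$ct <- parse_num(df$ct, "ct", path)
  df$dilution_factor <- suppressWarnings(as.numeric(df$dilution_factor))
  validate_ct(df[, cols])
}

validate_ct <- function(df) {
  bad_role <- !df$role %in% c("sample", "calibrator", "dilution")
  if (any(bad_role))
    stop("row ", which(bad_role)[1], ": unknown role '", df$role[bad_role][1], "'")
  if (any(df$ct <= 0))
    stop("row ", which(df$ct <= 0)[1], ": ct must be > 0")
  is_dil <- df$role == "dilution"
  if (any(is_dil & (is.na(df$dilution_factor) | df$dilution_factor <= 0)))
    stop("dilution wells require a positive dilution_factor")
  if (any(!is_dil & !is.na(df$dilution_factor)))
    stop("row ", which(!is_dil & !is.na(df$dilution_factor))[1],
         ": dilution_factor only allowed for role = dilution")
  key <- paste(df$sample_id, df$assay, df$role, df$dilution_factor,
               df$experiment_id, df$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated Ct well: ",
         gsub("\r", " / ", key[duplicated(key)][1]),
         " (duplicates are an error, not averaged)")
  rownames(df) <- NULL
  df
}

#' Read a clinical table
#'
#' Per-sample clinical covariates and follow-up: Breslow thickness in mm,
#' metastasis-free survival (`mfs_time` months, `mfs_event` 0/1) and
#' overall survival (`os_time`, `os_event`).
#'
#' @param path path to a TSV or CSV file.
#' @return validated `data.frame`.
#' @export
read_clinical_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- read_delimited(path, sep = sep)
  cols <- c("sample_id", "thickness_mm", "mfs_time", "mfs_event",
            "os_time", "os_event")
  need_columns(df, cols, path)
  if (nrow(df) == 0) return(df[, cols])
  df$sample_id <- as.character(df$sample_id)
  for (nm in cols[-1]) df[[nm]] <- parse_num(df[[nm]], nm, path)
  if (any(df$thickness_mm <= 0)) stop("thickness_mm must be positive")
  if (any(df$mfs_time < 0) || any(df$os_time < 0)) stop("survival times must be >= 0")
  if (!all(df$mfs_event %in% c(0, 1)) || !all(df$os_event %in% c(0, 1)))
    stop("event indicators must be 0/1")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  rownames(df) <- NULL
  df[, cols]
}

#' Write a TSV with a commented provenance header
#'
#' All pipeline writers emit tab-separated tables preceded by `#` comment
#' lines recording the package version, the table kind, run parameters and
#' (when run through the pipeline) the configuration hash. Readers in this
#' package skip `#` lines, so write/read round-trips are lossless.
#'
#' @param df data.frame to write (list columns are collapsed with commas).
#' @param path output path.
#' @param what short label for the table kind.
#' @param params named list of parameters to record in the header.
#' @param hash optional configuration hash string.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, what = "table", params = NULL, hash = NULL) {
  hdr <- c(sprintf("# mcramp %s %s", as.character(utils::packageVersion("mcramp")), what))
  if (length(params))
    hdr <- c(hdr, paste0("# params: ",
                         paste(names(params), unlist(lapply(params, format)),
                               sep = "=", collapse = "; ")))
  if (!is.null(hash)) hdr <- c(hdr, paste0("# config_hash: ", hash))
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(x, collapse = ","), "") else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the hotspot report
#'
#' One row per hotspot with 1-based inclusive coordinates, length, distinct
#' sample support, supporting sample ids and overlapping genes, ordered by
#' (chromosome, start).
#'
#' @param hotspots a hotspot table from [find_hotspots()] (optionally gene
#'   annotated by [annotate_genes()]).
#' @param path output TSV path.
#' @param params,hash forwarded to [write_tsv_report()].
#' @return `path`, invisibly.
#' @export
write_hotspot_report <- function(hotspots, path, params = NULL, hash = NULL) {
  df <- as.data.frame(hotspots)
  if (is.null(df$genes)) df$genes <- replicate(nrow(df), character(0), simplify = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  keep <- c("chrom", "start", "end", "length_bp", "support", "samples", "genes")
  write_tsv_report(df[, keep, drop = FALSE], path, "hotspot_report",
                   params = params, hash = hash)
}

#' @rdname read_segments
#' @param segments segment `data.frame` to write back out.
#' @param path output path.
#' @param params,hash forwarded to [write_tsv_report()].
#' @export
write_segments <- function(segments, path, params = NULL, hash = NULL) {
  write_tsv_report(segments, path, "segments", params = params, hash = hash)
}

#' @rdname read_ct_table
#' @param ct Ct `data.frame` to write back out.
#' @param params,hash forwarded to [write_tsv_report()].
#' @export
write_ct_table <- function(ct, path, params = NULL, hash = NULL) {
  write_tsv_report(ct, path, "ct_table", params = params, hash = hash)
}

#' @rdname read_clinical_table
#' @param clinical clinical `data.frame` to write back out.
#' @param params,hash forwarded to [write_tsv_report()].
#' @export
write_clinical_table <- function(clinical, path, params = NULL, hash = NULL) {
  write_tsv_report(clinical, path, "clinical", params = params, hash = hash)
}

# -- internal parsing helpers -------------------------------------------------

read_delimited <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    colClasses = "character", blank.lines.skip = TRUE)
}

need_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  invisible(df)
}

parse_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out))
    stop("malformed ", what, " in ", path, " at data row ", which(is.na(out))[1],
         ": '", x[which(is.na(out))[1]], "'")
  out
}

parse_coord <- function(x, what, path) {
  out <- parse_num(x, what, path)
  if (any(out < 1) || any(out != floor(out)))
    stop("malformed ", what, " in ", path, " at data row ",
         which(out < 1 | out != floor(out))[1], ": coordinates are 1-based integers")
  out
}
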