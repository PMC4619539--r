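#' Normalize chromosome names
#'
#' Chromosome labels are normalized to the `"chrN"` form on input (`"1"`,
#' `"Chr1"` and `"chr1"` all become `"chr1"`); after normalization,
#' comparisons are case-sensitive.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  paste0("chr", sub("^chr", "", chrom, ignore.case = TRUE))
}

#' Length of a genomic interval
#'
#' Coordinates are 1-based and inclusive throughout the package, so the
#' printed span chr1:156826196-157106439 has length
#' `157106439 - 156826196 + 1 = 280244` bp (~280 kb).
#'
#' @param start,end 1-based inclusive coordinates.
#' @return integer-valued length in bp.
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end < start")
  end - start + 1
}

# gap between [s1,e1] and a later [s2,e2] in 1-based inclusive coordinates:
# abutting intervals (s2 == e1 + 1) have gap 0.
interval_gap <- function(e1, s2) s2 - e1 - 1

#' @noRd
mc_log_level <- function() {
  lev <- getOption("mcramp.log_level", "info")
  match.arg(lev, c("quiet", "info", "debug"))
}

mc_log <- function(level = c("info", "debug"), ...) {
  level <- match.arg(level)
  thr <- mc_log_level()
  if (thr == "quiet") return(invisible(NULL))
  if (level == "debug" && thr != "debug") return(invisible(NULL))
  message(sprintf("[mcramp %s] %s", level, paste0(...)))
  invisible(NULL)
}

# djb2-style rolling hash of a canonical string rendering of an R object,
# reduced mod 2^31 - 1 (exact in doubles); used to stamp output files so
# runs with identical configuration are identifiable.
obj_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  config <- unclass(config)
  obj_hash(config[order(names(config))])
}

# Deterministic fan-out of one user-facing seed into per-component child
# seeds: the global seed initializes R's RNG once, from which k child seeds
# are drawn; each component then calls set.seed(child). Keeps components
# reproducible independently of how many random draws their siblings make.
fanout_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
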