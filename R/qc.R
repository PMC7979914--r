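# Phred-based read quality filtering. Two published criteria are provided:
# a fraction filter (>= 90% of bases at Q >= 25, the pipeline default) and a
# lower-quartile filter (25th percentile of base qualities >= 37).

#' Configure the Phred quality filter
#'
#' @param mode `"fraction_threshold"`: a read passes when at least
#'   `min_fraction` of its bases have quality >= `min_q`;
#'   `"lower_quartile"`: a read passes when the nearest-rank 25th percentile
#'   of its base qualities is >= `min_q`.
#' @param min_q minimum Phred score, 0-41.
#' @param min_fraction required fraction of bases at or above `min_q`
#'   (fraction mode only).
#' @return a `qc_config` list.
#' @export
qc_config <- function(mode = c("fraction_threshold", "lower_quartile"),
                      min_q = 25L, min_fraction = 0.9) {
  mode <- match.arg(mode)
  stopifnot(min_q >= 0, min_q <= 41, min_fraction > 0, min_fraction <= 1)
  structure(list(mode = mode, min_q = as.integer(min_q),
                 min_fraction = min_fraction), class = "qc_config")
}

# Nearest-rank (type 1) lower quartile of integer qualities.
lower_quartile <- function(q) quantile(q, 0.25, type = 1, names = FALSE)

#' Filter reads by per-base Phred quality
#'
#' Applies a [qc_config()] criterion to each read. Empty reads never pass and
#' are counted separately. The filter is idempotent and monotone in `min_q`.
#'
#' @param reads read tibble (columns `read_id`, `nt_sequence`, `quality`).
#' @param cfg a [qc_config()].
#' @return the passing reads; attrition counts are attached as the
#'   `"qc_stats"` attribute and available via [qc_stats()].
#' @export
filter_by_phred <- function(reads, cfg = qc_config()) {
  qs <- phred_to_int(reads$quality)
  empty <- lengths(qs) == 0L | nchar(reads$nt_sequence) == 0L
  pass <- switch(cfg$mode,
    fraction_threshold = vapply(qs, function(q)
      length(q) > 0L && sum(q >= cfg$min_q) / length(q) >= cfg$min_fraction,
      logical(1)),
    lower_quartile = vapply(qs, function(q)
      length(q) > 0L && lower_quartile(q) >= cfg$min_q, logical(1)))
  pass <- pass & !empty
  out <- reads[pass, , drop = FALSE]
  attr(out, "qc_stats") <- tibble::tibble(
    reads_in = nrow(reads), reads_passed = sum(pass),
    failed_quality = sum(!pass & !empty), failed_empty = sum(empty),
    mode = cfg$mode, min_q = cfg$min_q)
  out
}

#' @rdname filter_by_phred
#' @param filtered result of [filter_by_phred()].
#' @export
qc_stats <- function(filtered) {
  s <- attr(filtered, "qc_stats")
  if (is.null(s)) stop("no qc_stats attribute; was this tibble produced by filter_by_phred()?")
  s
}
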