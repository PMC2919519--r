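#' Call clusters (peaks) by runs of probes above a quantile threshold
#'
#' A cluster is a maximal run of at least `min_run` consecutive probes
#' whose values lie strictly above the empirical `quantile_threshold`
#' quantile of the track (type-7, linear-interpolation quantile). With
#' 50-bp probe spacing the default `min_run = 4` corresponds to ~150 bp.
#' Strict inequality means a constant track calls no clusters. The input
#' must be a single contiguous stretch in genomic order; split by
#' chromosome upstream so runs never span chromosomes.
#'
#' @param values Numeric probe signal vector in genomic order.
#' @param quantile_threshold Quantile `q` in (0, 1); probes above the
#'   q-th quantile are "high".
#' @param min_run Minimum run length to call a cluster (default 4).
#' @return Object of class `cluster_calls`: list with `intervals` (data
#'   frame `start`, `end`, `length`; 1-based inclusive probe indices),
#'   `mask` (logical, `TRUE` exactly for probes inside called clusters),
#'   `threshold_value`, `quantile_threshold`, `min_run`.
#' @examples
#' v <- c(rep(0, 8), rep(5, 4), rep(0, 8))
#' call_clusters(v, 0.8, min_run = 4)$intervals
#' @export
call_clusters <- function(values, quantile_threshold, min_run = 4L) {
  if (length(values) == 0L) stop_data("empty probe track")
  if (quantile_threshold <= 0 || quantile_threshold >= 1) {
    stop_parameter("quantile_threshold must lie strictly in (0, 1)")
  }
  min_run <- as.integer(min_run)
  if (min_run < 1L) stop_parameter("min_run must be >= 1")
  if (length(values) < min_run) {
    stop_data("track shorter than min_run")
  }
  thr <- stats::quantile(values, quantile_threshold, names = FALSE)
  high <- values > thr
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  intervals <- data.frame(start = starts[keep], end = ends[keep],
                          length = r$lengths[keep])
  mask <- logical(length(values))
  if (nrow(intervals)) {
    mask[unlist(Map(seq.int, intervals$start, intervals$end))] <- TRUE
  }
  structure(list(intervals = intervals, mask = mask,
                 threshold_value = thr,
                 quantile_threshold = quantile_threshold,
                 min_run = min_run),
            class = "cluster_calls")
}

#' @export
print.cluster_calls <- function(x, ...) {
  cat(sprintf(
    "cluster_calls: %d clusters (%d probes) above q=%.3f (value %.4g), min_run=%d\n",
    nrow(x$intervals), sum(x$mask), x$quantile_threshold,
    x$threshold_value, x$min_run))
  invisible(x)
}

#' Binary cluster-membership concordance between replicates
#'
#' Pearson correlation of the two 0/1 cluster-membership vectors —
#' equivalently the phi coefficient of the 2x2 probe overlap table. Probes
#' inside a called cluster are 1, the rest 0, and the correlation measures
#' how well the called regions agree between replicates.
#'
#' @param mask_x,mask_y Logical (or 0/1) vectors of equal length.
#' @return Correlation in \[-1, 1\]. A constant mask (no clusters, or all
#'   probes in clusters) raises a typed undefined-correlation error; see
#'   [concordance_curve()] which flags such thresholds instead.
#' @export
binary_concordance <- function(mask_x, mask_y) {
  if (length(mask_x) != length(mask_y)) {
    stop_data("masks differ in length")
  }
  x <- as.numeric(mask_x)
  y <- as.numeric(mask_y)
  check_nonconstant(x, "mask_x")
  check_nonconstant(y, "mask_y")
  stats::cor(x, y)
}

#' Cluster-level concordance as a function of quantile threshold
#'
#' Calls clusters independently in each replicate at every threshold of
#' the grid, computes the binary concordance, and records the curve and
#' its maximum. Thresholds at which either replicate has a constant mask
#' (typically: no clusters called) are reported as `NA` — flagged, not
#' silently dropped — and excluded from the maximum.
#'
#' @param pair A [paired_replicates()] object in genomic order.
#' @param thresholds Quantile grid in (0, 1); default 0.80 to 0.995 in
#'   steps of 0.005.
#' @param min_run Minimum cluster run length (default 4).
#' @return Object of class `concordance_curve`: data frame with columns
#'   `threshold` and `concordance` (NA where undefined), with attributes
#'   `max_correlation` and `argmax_threshold`.
#' @export
concordance_curve <- function(pair, thresholds = seq(0.80, 0.995, by = 0.005),
                              min_run = 4L) {
  pair <- as_paired(pair)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_parameter("all thresholds must lie strictly in (0, 1)")
  }
  conc <- vapply(thresholds, function(q) {
    cx <- call_clusters(pair$values_x, q, min_run)
    cy <- call_clusters(pair$values_y, q, min_run)
    tryCatch(binary_concordance(cx$mask, cy$mask),
             quantcorr_undefined_correlation = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(conc))) {
    stop_data("concordance undefined at every threshold of the grid")
  }
  out <- data.frame(threshold = thresholds, concordance = conc)
  structure(out, class = c("concordance_curve", "data.frame"),
            max_correlation = max(conc, na.rm = TRUE),
            argmax_threshold = thresholds[which.max(conc)],
            min_run = as.integer(min_run))
}

#' @export
print.concordance_curve <- function(x, ...) {
  cat(sprintf(
    "concordance_curve: %d thresholds (%d undefined); max %.4f at q=%.3f\n",
    nrow(x), sum(is.na(x$concordance)),
    attr(x, "max_correlation"), attr(x, "argmax_threshold")))
  invisible(x)
}

#' Convert probe-index cluster intervals to genomic BED intervals
#'
#' Maps 1-based inclusive probe-index intervals (as returned by
#' [call_clusters()]) onto the genomic coordinates of a probe track:
#' a cluster spans from the start of its first probe to the end of its
#' last probe, in 0-based half-open BED convention.
#'
#' @param intervals Data frame with `start`, `end` probe indices.
#' @param track A `probe_track` (see [read_track()]) whose rows correspond
#'   positionally to the probes the intervals index.
#' @return Data frame `chrom`, `start`, `end` suitable for
#'   [write_intervals()].
#' @export
cluster_intervals_to_bed <- function(intervals, track) {
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  if (max(intervals$end) > nrow(track)) {
    stop_data("interval indices exceed track length")
  }
  chrom_first <- track$chrom[intervals$start]
  chrom_last <- track$chrom[intervals$end]
  if (any(chrom_first != chrom_last)) {
    stop_data("a cluster spans a chromosome boundary; split tracks upstream")
  }
  data.frame(chrom = chrom_first,
             start = track$start[intervals$start],
             end = track$end[intervals$end])
}
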