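#' Paired replicate probe tracks
#'
#' Container for two aligned probe-level signal vectors from replicate
#' tiling-array (e.g. ChIP-chip) experiments. All correlation statistics in
#' the package operate on this object. Pairing and filtering (coordinate
#' matching, removal of non-finite values) happen upstream in
#' [align_replicates()]; this constructor only validates.
#'
#' @param values_x Numeric vector of probe signals for replicate 1
#'   (typically log-ratios; arbitrary units).
#' @param values_y Numeric vector for replicate 2, same probes, same order.
#' @param probe_keys Optional character vector of probe identifiers
#'   (coordinate strings or array IDs) carried through from I/O.
#'
#' @return An object of class `paired_replicates`: a list with elements
#'   `values_x`, `values_y`, `n`, and `probe_keys` (possibly `NULL`).
#' @examples
#' pr <- paired_replicates(c(0.1, 1.2, 0.3), c(0.2, 1.1, 0.4))
#' pr$n
#' @export
paired_replicates <- function(values_x, values_y, probe_keys = NULL) {
  values_x <- as.numeric(values_x)
  values_y <- as.numeric(values_y)
  if (length(values_x) != length(values_y)) {
    stop_data(sprintf(
      "replicate vectors differ in length (%d vs %d)",
      length(values_x), length(values_y)))
  }
  n <- length(values_x)
  if (n < 2L) {
    stop_data("need at least 2 paired probes")
  }
  if (anyNA(values_x) || anyNA(values_y) ||
      any(!is.finite(values_x)) || any(!is.finite(values_y))) {
    stop_data("probe values must be finite and non-missing; filter upstream")
  }
  if (!is.null(probe_keys) && length(probe_keys) != n) {
    stop_data("probe_keys length must match the value vectors")
  }
  structure(
    list(values_x = values_x, values_y = values_y, n = n,
         probe_keys = probe_keys),
    class = "paired_replicates")
}

#' @export
print.paired_replicates <- function(x, ...) {
  cat(sprintf("paired_replicates: %d probes%s\n", x$n,
              if (is.null(x$probe_keys)) "" else " (with probe keys)"))
  invisible(x)
}

as_paired <- function(pair) {
  if (inherits(pair, "paired_replicates")) return(pair)
  stop_data("expected a paired_replicates object")
}
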