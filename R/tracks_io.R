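#' Read a probe-level signal track
#'
#' Reads a probe track from disk into a validated `probe_track` data
#' frame: columns `chrom`, `start` (0-based inclusive), `end` (exclusive),
#' `value`, and optionally `id`. Two formats are supported:
#'
#' * `"bedgraph"` — four whitespace-delimited columns
#'   (chrom, start, end, value), no header required; `track` and `#`
#'   lines are skipped.
#' * `"tsv"` — tab-delimited with a header line; either
#'   `chrom`/`start`/`end`/`value` (plus optional `id`) or just
#'   `id`/`value` for coordinate-free probe sets.
#'
#' Rows with non-finite values are dropped (count reported via
#' `message()`); duplicate probe keys keep the first occurrence; output is
#' sorted by (chrom, start) or by id for coordinate-free tracks. Values
#' are used as-is — no normalization.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.bedgraph`/`.bdg` vs `.tsv`/
#'   `.txt`), `"bedgraph"`, or `"tsv"`.
#' @return Data frame of class `probe_track`.
#' @export
read_track <- function(path, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bedgraph", "bdg")) "bedgraph" else "tsv"
  }
  lines <- readLines(path)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop_data(sprintf("empty track file: %s", path))
  }
  if (format == "bedgraph") {
    df <- parse_bedgraph(lines, path)
  } else {
    df <- parse_track_tsv(lines, path)
  }
  finalize_track(df, path)
}

parse_bedgraph <- function(lines, path) {
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- lineno[which(nf != 4L)[1]]
    stop_data(sprintf("%s line %d: expected 4 columns, got %d",
                      path, bad, nf[which(nf != 4L)[1]]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_data(sprintf("%s line %d: non-integer coordinates",
                      path, lineno[bad[1]]))
  }
  data.frame(chrom = m[, 1], start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

parse_track_tsv <- function(lines, path) {
  df <- tryCatch(
    utils::read.delim(text = lines, stringsAsFactors = FALSE),
    error = function(e) stop_data(sprintf("%s: parse error: %s", path,
                                          conditionMessage(e))))
  nms <- tolower(names(df))
  names(df) <- nms
  if (all(c("chrom", "start", "end", "value") %in% nms)) {
    keep <- intersect(c("chrom", "start", "end", "value", "id"), nms)
    df <- df[keep]
  } else if (all(c("id", "value") %in% nms)) {
    df <- data.frame(chrom = NA_character_, start = NA_integer_,
                     end = NA_integer_, value = df$value, id = df$id,
                     stringsAsFactors = FALSE)
  } else {
    stop_data(sprintf(
      "%s: header must provide chrom/start/end/value or id/value", path))
  }
  df$value <- suppressWarnings(as.numeric(df$value))
  df
}

finalize_track <- function(df, path) {
  ok <- is.finite(df$value)
  if (any(!ok)) {
    message(sprintf("read_track: dropped %d non-finite value(s) from %s",
                    sum(!ok), path))
    df <- df[ok, , drop = FALSE]
  }
  if (!nrow(df)) stop_data(sprintf("no usable probes in %s", path))
  has_coords <- !all(is.na(df$start))
  if (has_coords) {
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    key <- paste(df$chrom, df$start, df$end)
  } else {
    df <- df[order(df$id), , drop = FALSE]
    key <- df$id
  }
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("read_track: %d duplicate probe key(s) in %s; kept first",
                    sum(dup), path))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("probe_track", "data.frame"))
}

track_key <- function(track) {
  if ("id" %in% names(track) && !all(is.na(track$id))) {
    track$id
  } else {
    paste(track$chrom, track$start, track$end)
  }
}

#' Align two replicate tracks into a paired-replicates object
#'
#' Matches probes exactly on (chrom, start, end) — or on probe ID when
#' both tracks carry one — and keeps only the intersection, in genomic
#' order (so cluster calling downstream sees consecutive probes).
#' Unmatched probe counts on each side are reported via `message()`.
#'
#' @param track_a,track_b `probe_track` objects from [read_track()].
#' @return A [paired_replicates()] object with `probe_keys` set.
#' @export
align_replicates <- function(track_a, track_b) {
  if (!nrow(track_a) || !nrow(track_b)) stop_data("empty input track")
  key_a <- track_key(track_a)
  key_b <- track_key(track_b)
  idx_b <- match(key_a, key_b)
  keep <- !is.na(idx_b)
  if (!any(keep)) stop_data("no probes shared between the two tracks")
  n_un_a <- sum(!keep)
  n_un_b <- nrow(track_b) - sum(keep)
  if (n_un_a || n_un_b) {
    message(sprintf(
      "align_replicates: dropped %d unmatched probe(s) from A, %d from B",
      n_un_a, n_un_b))
  }
  paired_replicates(track_a$value[keep], track_b$value[idx_b[keep]],
                    probe_keys = key_a[keep])
}

#' Write a probe track to disk
#'
#' Writes a `probe_track` losslessly in either format accepted by
#' [read_track()] (bedGraph: 4 columns, no header; tsv: tab-delimited
#' with header).
#'
#' @param track A `probe_track`.
#' @param path Output path.
#' @param format `"bedgraph"` or `"tsv"`.
#' @export
write_track <- function(track, path, format = c("bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "bedgraph") {
    out <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   format(track$value, trim = TRUE, digits = 15))
    writeLines(out, path)
  } else {
    utils::write.table(as.data.frame(track), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write cluster intervals as a BED file
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based,
#'   half-open), e.g. from [cluster_intervals_to_bed()].
#' @param path Output path. An empty interval set produces an empty file.
#' @export
write_intervals <- function(intervals, path) {
  if (!nrow(intervals)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start),
                     as.integer(intervals$end)), path)
  invisible(path)
}
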