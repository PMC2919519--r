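#' Pearson correlation of paired replicate tracks
#'
#' Standard sample Pearson correlation of the two probe-value vectors.
#' Constant inputs signal a typed undefined-correlation error rather than
#' returning `NA`, because a silent `NA` propagating through a sweep hides
#' degenerate simulations.
#'
#' @param pair A [paired_replicates()] object.
#' @return Correlation in \[-1, 1\].
#' @examples
#' pearson_correlation(paired_replicates(1:4, c(1, 2, 3, 5)))
#' @export
pearson_correlation <- function(pair) {
  pair <- as_paired(pair)
  check_nonconstant(pair$values_x, "values_x")
  check_nonconstant(pair$values_y, "values_y")
  stats::cor(pair$values_x, pair$values_y)
}

#' Spearman correlation of paired replicate tracks
#'
#' Pearson correlation of the rank-transformed vectors; ties receive
#' average (midrank) ranks, the usual convention.
#'
#' @inheritParams pearson_correlation
#' @return Correlation in \[-1, 1\].
#' @export
spearman_correlation <- function(pair) {
  pair <- as_paired(pair)
  check_nonconstant(pair$values_x, "values_x")
  check_nonconstant(pair$values_y, "values_y")
  stats::cor(pair$values_x, pair$values_y, method = "spearman")
}

check_nonconstant <- function(v, what) {
  if (min(v) == max(v)) {
    stop_undefined_correlation(
      sprintf("correlation undefined: %s is constant", what))
  }
  invisible(TRUE)
}

#' Equal-count quantile binning of probe signals
#'
#' Bins a signal vector into `n_bins` groups of (as near as possible) equal
#' probe count by rank, label 1 for the smallest values. Bin `k` spans ranks
#' `(ceiling((k-1)*n/B), ceiling(k*n/B)]`, so when `n_bins` does not divide
#' `n` the bin sizes differ by at most one probe. Ties are broken by stable
#' input order: tied values straddling a block boundary are split, which
#' guarantees exactly balanced bins (tiling-array log-ratios contain ties,
#' so this rule is deterministic and documented rather than hidden).
#'
#' @param values Numeric vector, length `n >= n_bins`.
#' @param n_bins Integer number of bins `B0`, between 2 and `n`.
#' @return Integer vector of bin labels in `1..n_bins`, same length as
#'   `values`; every bin non-empty.
#' @examples
#' quantize_equal_count(c(0.3, -1, 5, 2, 0), 5)  # one probe per bin: ranks
#' @export
quantize_equal_count <- function(values, n_bins) {
  n <- length(values)
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2L) {
    stop_parameter("n_bins must be an integer >= 2")
  }
  if (n_bins > n) {
    stop_parameter(sprintf("n_bins (%d) exceeds number of probes (%d)",
                           n_bins, n))
  }
  if (anyNA(values)) stop_data("values must not contain NA")
  ranks <- integer(n)
  ranks[order(values)] <- seq_len(n)  # stable: ties keep input order
  cuts <- ceiling(seq_len(n_bins) * (n / n_bins))
  cuts[n_bins] <- n  # guard fp at the top edge
  bin_of_rank <- rep.int(seq_len(n_bins), diff(c(0L, cuts)))
  bin_of_rank[ranks]
}

#' Joint contingency table of two bin-label vectors
#'
#' Entry `(a, b)` counts probes with label `a` in replicate 1 and `b` in
#' replicate 2. The table is the working representation for the merge
#' search: every candidate correlation is evaluated from it without
#' rescanning the `n` probes.
#'
#' @param labels_x,labels_y Integer label vectors in `1..n_bins`, equal
#'   length.
#' @param n_bins Number of bins `B` (table dimension).
#' @return `n_bins` x `n_bins` integer matrix with total `n`.
#' @export
joint_contingency <- function(labels_x, labels_y, n_bins) {
  n_bins <- as.integer(n_bins)
  if (length(labels_x) != length(labels_y)) {
    stop_data("label vectors differ in length")
  }
  rng <- range(labels_x, labels_y)
  if (rng[1] < 1L || rng[2] > n_bins) {
    stop_data(sprintf("labels outside 1..%d", n_bins))
  }
  counts <- tabulate((labels_x - 1L) * n_bins + labels_y,
                     nbins = n_bins * n_bins)
  matrix(counts, nrow = n_bins, byrow = TRUE)
}

# Moment-based Pearson. Returns NA_real_ on zero variance; exported wrapper
# turns that into a typed error.
pcc_from_moments <- function(n, sx, sy, sxx, syy, sxy) {
  vx <- n * sxx - sx * sx
  vy <- n * syy - sy * sy
  if (vx <= 0 || vy <= 0) return(NA_real_)
  (n * sxy - sx * sy) / sqrt(vx * vy)
}

contingency_moments <- function(tab) {
  B <- nrow(tab)
  a <- seq_len(B)
  r <- rowSums(tab)
  cs <- colSums(tab)
  list(n = sum(r), a = a, r = r, cs = cs,
       sx = sum(a * r), sy = sum(a * cs),
       sxx = sum(a * a * r), syy = sum(a * a * cs),
       sxy = drop(rbind(a) %*% tab %*% cbind(a)))
}

#' Pearson correlation from a label contingency table
#'
#' Computes the Pearson correlation of the two label vectors summarized by
#' a joint contingency table, exactly (to floating point) but at a cost
#' independent of the number of probes: only the table's first and second
#' moments are needed.
#'
#' @param tab Square count matrix as produced by [joint_contingency()].
#' @return Correlation of the expanded label vectors.
#' @export
pearson_from_contingency <- function(tab) {
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) {
    stop_data("expected a square contingency matrix")
  }
  m <- contingency_moments(tab)
  if (m$n < 2) stop_data("contingency table must hold at least 2 probes")
  val <- pcc_from_moments(m$n, m$sx, m$sy, m$sxx, m$syy, m$sxy)
  if (is.na(val)) {
    stop_undefined_correlation(
      "correlation undefined: a margin is concentrated in one bin")
  }
  val
}

# Collapse bins k and k+1 on both axes of the joint table.
merge_table <- function(tab, k) {
  tab[k, ] <- tab[k, ] + tab[k + 1L, ]
  tab <- tab[-(k + 1L), , drop = FALSE]
  tab[, k] <- tab[, k] + tab[, k + 1L]
  tab[, -(k + 1L), drop = FALSE]
}

#' Evaluate all adjacent-bin merge candidates
#'
#' With `B` bins there are `B - 1` ways to merge two consecutive bins. The
#' same merge is applied to both replicates (one shared bin structure), and
#' the Pearson correlation of the relabelled vectors `1..B-1` is computed
#' for each candidate. Evaluation is done from the joint contingency table
#' with suffix-sum moment updates, so each candidate costs O(1) after an
#' O(B^2) precompute.
#'
#' @param tab Joint contingency table with `B >= 3` bins per side.
#' @return Data frame with columns `candidate` (bin index `k`, meaning
#'   "merge bins k and k+1") and `correlation` (the post-merge Pearson;
#'   `NA` where the merged configuration has zero variance on a margin).
#' @export
evaluate_merge_candidates <- function(tab) {
  B <- nrow(tab)
  if (!is.matrix(tab) || B != ncol(tab)) {
    stop_data("expected a square contingency matrix")
  }
  if (B < 3L) {
    stop_parameter("need at least 3 bins to have admissible merge candidates")
  }
  m <- contingency_moments(tab)
  a <- m$a
  # suffix sums over rows/columns strictly above k, i.e. indices >= k+1
  suf <- function(v) rev(cumsum(rev(v)))            # suf[j] = sum_{i>=j} v
  suf_r   <- suf(m$r);        suf_c   <- suf(m$cs)
  suf_ar  <- suf(a * m$r);    suf_ac  <- suf(a * m$cs)
  u <- drop(tab %*% a)   # row a: sum_b b*T[a,b]
  v <- drop(a %*% tab)   # col b: sum_a a*T[a,b]
  suf_u <- suf(u); suf_v <- suf(v)
  # 2D suffix sums: S2[i,j] = sum_{a>=i, b>=j} T[a,b]
  s2 <- apply(tab, 1L, function(row) rev(cumsum(rev(row))))  # transposed
  s2 <- apply(s2, 1L, function(col) rev(cumsum(rev(col))))   # back: [i,j]
  ks <- seq_len(B - 1L)
  corr <- vapply(ks, function(k) {
    j <- k + 1L
    sx  <- m$sx  - suf_r[j]
    sy  <- m$sy  - suf_c[j]
    sxx <- m$sxx - 2 * suf_ar[j] + suf_r[j]
    syy <- m$syy - 2 * suf_ac[j] + suf_c[j]
    sxy <- m$sxy - suf_u[j] - suf_v[j] + s2[j, j]
    pcc_from_moments(m$n, sx, sy, sxx, syy, sxy)
  }, numeric(1))
  data.frame(candidate = ks, correlation = corr)
}

#' Quantized correlation coefficient (QCC)
#'
#' Reproducibility statistic for replicate probe-level tracks that is
#' robust to the fraction of probes carrying signal. Both replicates are
#' first discretized into `initial_bins` equal-count quantile bins
#' (label 1 = lowest signal). Then, greedily, the single merge of two
#' adjacent bins (applied to both replicates simultaneously, so one shared
#' bin structure) that most improves the Pearson correlation of the label
#' vectors is performed, until no merge strictly improves it. Collapsing
#' the background bins into one group suppresses the noise contribution
#' that otherwise couples the plain Pearson correlation to signal coverage.
#'
#' The search is local (merged bins are never split again); total merges
#' are at most `initial_bins - 2` and candidate evaluations are capped at
#' `initial_bins * (initial_bins - 1) / 2`. Ties among equally good merge
#' candidates (within 1e-12) go to the lowest bin index, which makes the
#' result deterministic and symmetric under swapping the replicates.
#' "No longer improves" means no candidate exceeds the current correlation
#' by more than 1e-12; at least 2 bins always remain.
#'
#' @param pair A [paired_replicates()] object with `n >= initial_bins`.
#' @param initial_bins Starting bin count `B0` (default 100; raise it for
#'   very high signal-to-noise data with low coverage).
#' @return Object of class `qcc_result` with elements `qcc` (the
#'   statistic), `initial_pcc_quantized` (label correlation before any
#'   merge), `merge_trace` (data frame of `merged_bin`, `correlation`,
#'   strictly increasing), `final_state` (bin structure: `B`, rank
#'   boundaries, per-probe labels, joint table, `current_pcc`), `raw_pcc`,
#'   `spearman`, `n_probes`, `initial_bins`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500); pr <- paired_replicates(x, x + rnorm(500, sd = 0.5))
#' res <- qcc(pr, initial_bins = 20)
#' res$qcc >= res$initial_pcc_quantized
#' @export
qcc <- function(pair, initial_bins = 100) {
  pair <- as_paired(pair)
  B0 <- as.integer(initial_bins)
  if (length(B0) != 1L || is.na(B0) || B0 < 2L) {
    stop_parameter("initial_bins must be an integer >= 2")
  }
  if (B0 > pair$n) {
    stop_parameter(sprintf(
      "initial_bins (%d) exceeds number of probes (%d)", B0, pair$n))
  }
  raw_pcc <- pearson_correlation(pair)   # errors on constant input
  spearman <- spearman_correlation(pair)

  lx <- quantize_equal_count(pair$values_x, B0)
  ly <- quantize_equal_count(pair$values_y, B0)
  tab <- joint_contingency(lx, ly, B0)
  cur <- pearson_from_contingency(tab)
  initial_pcc <- cur

  eps <- 1e-12
  cap <- B0 * (B0 - 1) / 2
  evals <- 0L
  upper <- seq_len(B0)  # original-bin index of each current bin's top
  trace_bin <- integer(0)
  trace_cor <- numeric(0)
  B <- B0
  while (B > 2L) {
    cand <- evaluate_merge_candidates(tab)
    evals <- evals + (B - 1L)
    if (evals > cap) {
      stop_internal("candidate evaluation cap B0*(B0-1)/2 exceeded")
    }
    ok <- which(!is.na(cand$correlation))
    if (!length(ok)) break
    mx <- max(cand$correlation[ok])
    if (mx <= cur + eps) break
    k <- min(ok[cand$correlation[ok] >= mx - eps])  # lowest-index tie rule
    tab <- merge_table(tab, k)
    upper <- upper[-k]
    B <- B - 1L
    cur <- cand$correlation[k]
    trace_bin <- c(trace_bin, k)
    trace_cor <- c(trace_cor, cur)
  }

  # map original labels onto the final merged bins
  bin_map <- rep.int(seq_along(upper), diff(c(0L, upper)))
  n <- pair$n
  rank_cuts <- ceiling(upper * (n / B0))
  rank_cuts[length(rank_cuts)] <- n
  final_state <- structure(list(
    B = B,
    initial_bins = B0,
    boundaries_x = rank_cuts,   # rank-space cut positions; quantile bins
    boundaries_y = rank_cuts,   # share one structure across replicates
    labels_x = bin_map[lx],
    labels_y = bin_map[ly],
    joint_counts = tab,
    current_pcc = cur), class = "quantization_state")

  structure(list(
    qcc = cur,
    initial_pcc_quantized = initial_pcc,
    merge_trace = data.frame(merged_bin = trace_bin,
                             correlation = trace_cor),
    final_state = final_state,
    raw_pcc = raw_pcc,
    spearman = spearman,
    n_probes = n,
    initial_bins = B0), class = "qcc_result")
}

#' @export
print.qcc_result <- function(x, ...) {
  cat("Quantized correlation coefficient\n")
  cat(sprintf("  probes:            %d\n", x$n_probes))
  cat(sprintf("  initial bins (B0): %d\n", x$initial_bins))
  cat(sprintf("  final bins:        %d (%d merges)\n",
              x$final_state$B, nrow(x$merge_trace)))
  cat(sprintf("  Pearson (raw):     %.4f\n", x$raw_pcc))
  cat(sprintf("  Spearman:          %.4f\n", x$spearman))
  cat(sprintf("  QCC:               %.4f\n", x$qcc))
  invisible(x)
}

#' Expected Pearson correlation of the two-group simulation model
#'
#' Closed-form population Pearson correlation for replicate tracks where a
#' fraction `coverage` of probes carries mean signal `snr * noise_sd` in
#' both replicates and every probe receives independent Gaussian noise of
#' standard deviation `noise_sd`. The shared signal contributes
#' between-probe variance `p(1-p) (S sigma)^2` to each replicate and all of
#' the covariance, giving `p(1-p) S^2 / (p(1-p) S^2 + 1)` — independent of
#' `noise_sd`, since the signal mean is expressed in noise-sd units.
#' Used to validate the simulator's calibration.
#'
#' @param coverage Signal coverage fraction `p` in \[0, 1\].
#' @param snr Signal-to-noise ratio `S >= 0`.
#' @param noise_sd Noise standard deviation (must be positive; does not
#'   affect the value — kept as an argument to mirror the simulator).
#' @return Expected Pearson correlation.
#' @examples
#' analytic_expected_pcc(0.05, 3)  # ~0.2995
#' analytic_expected_pcc(0.20, 3)  # ~0.5902
#' @export
analytic_expected_pcc <- function(coverage, snr, noise_sd = 1) {
  if (any(coverage < 0 | coverage > 1)) {
    stop_parameter("coverage must lie in [0, 1]")
  }
  if (any(snr < 0)) stop_parameter("snr must be >= 0")
  if (any(noise_sd <= 0)) stop_parameter("noise_sd must be > 0")
  v <- coverage * (1 - coverage) * snr^2
  v / (v + 1)
}
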