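#' Simulation configuration for synthetic replicate tracks
#'
#' The synthetic ChIP-chip model has exactly two scientific parameters:
#' signal coverage (fraction of probes carrying binding signal) and the
#' signal-to-noise ratio (signal mean in units of the noise standard
#' deviation). Defaults follow typical high-density tiling-array designs:
#' 300,000 probes and unit Gaussian noise.
#'
#' @param n_probes Total probe count (default 300000).
#' @param coverage Fraction `p` of probes carrying signal, in \[0, 1\].
#' @param snr Signal mean in noise-sd units, `S >= 0`.
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param seed Integer seed for the random stream.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 300000L, coverage, snr,
                              noise_sd = 1, seed = 1L) {
  n_probes <- as.integer(n_probes)
  if (is.na(n_probes) || n_probes < 2L) {
    stop_parameter("n_probes must be >= 2")
  }
  if (coverage < 0 || coverage > 1) stop_parameter("coverage must be in [0,1]")
  if (snr < 0) stop_parameter("snr must be >= 0")
  if (noise_sd <= 0) stop_parameter("noise_sd must be > 0")
  structure(list(n_probes = n_probes, coverage = coverage, snr = snr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a pair of replicate probe tracks
#'
#' The first `floor(coverage * n_probes)` probes carry underlying mean
#' `snr * noise_sd` in BOTH replicates (binding positions are shared
#' between replicates — reproducibility of the signal is what the
#' statistics measure); the remaining probes have mean 0. Independent
#' `N(0, noise_sd^2)` noise is added to every probe in each replicate.
#' Probe order is irrelevant to every statistic computed on the pair, so
#' signal placement at the head of the vector loses no generality.
#' Seeded runs are bit-reproducible.
#'
#' @param config A [simulation_config()].
#' @return A [paired_replicates()] object with attribute `signal_mask`
#'   (logical, `TRUE` where the probe carries signal).
#' @examples
#' pr <- simulate_replicate_pair(simulation_config(1000, 0.05, 3, seed = 7))
#' sum(attr(pr, "signal_mask"))  # 50
#' @export
simulate_replicate_pair <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_parameter("config must be a simulation_config")
  }
  n <- config$n_probes
  n_sig <- floor(config$coverage * n)
  mask <- c(rep(TRUE, n_sig), rep(FALSE, n - n_sig))
  mu <- ifelse(mask, config$snr * config$noise_sd, 0)
  set.seed(config$seed)
  x <- mu + stats::rnorm(n, sd = config$noise_sd)
  y <- mu + stats::rnorm(n, sd = config$noise_sd)
  pr <- paired_replicates(x, y)
  attr(pr, "signal_mask") <- mask
  pr
}

# One seeded parent stream hands a child seed to every replicate pair, so
# cells of a sweep are reproducible independently of evaluation order.
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

ci_half_width <- function(v) {
  1.96 * stats::sd(v) / sqrt(length(v))
}

sweep_row <- function(stats_mat, statistic) {
  data.frame(statistic = statistic,
             mean = mean(stats_mat),
             ci_half = ci_half_width(stats_mat),
             reps = length(stats_mat))
}

compute_cell <- function(n_probes, coverage, snr, noise_sd, initial_bins,
                         seeds, statistics) {
  vals <- list(pearson = numeric(0), spearman = numeric(0),
               qcc = numeric(0))
  for (s in seeds) {
    pr <- simulate_replicate_pair(
      simulation_config(n_probes, coverage, snr, noise_sd, seed = s))
    if ("qcc" %in% statistics) {
      res <- qcc(pr, initial_bins = initial_bins)
      vals$qcc <- c(vals$qcc, res$qcc)
      if ("pearson" %in% statistics) vals$pearson <- c(vals$pearson, res$raw_pcc)
      if ("spearman" %in% statistics) vals$spearman <- c(vals$spearman, res$spearman)
    } else {
      if ("pearson" %in% statistics) {
        vals$pearson <- c(vals$pearson, pearson_correlation(pr))
      }
      if ("spearman" %in% statistics) {
        vals$spearman <- c(vals$spearman, spearman_correlation(pr))
      }
    }
  }
  do.call(rbind, lapply(statistics, function(st) {
    data.frame(statistic = st, mean = mean(vals[[st]]),
               ci_half = ci_half_width(vals[[st]]),
               reps = length(vals[[st]]))
  }))
}

#' Sweep correlation statistics over a signal-coverage grid
#'
#' For each (snr, coverage) cell, simulates `reps` replicate pairs and
#' records the mean and 95% confidence half-width (1.96 * SE) of the
#' requested statistics. This is the experiment showing that the plain
#' Pearson correlation tracks signal coverage while QCC stays nearly flat.
#'
#' @param snr Vector of signal-to-noise ratios to sweep.
#' @param coverage Coverage grid (default 5%–50% in steps of 5%).
#' @param reps Simulated pairs per cell (`>= 2`; 100 matches the full
#'   study, 10–30 suffices for confidence-interval checks).
#' @param initial_bins `B0` passed to [qcc()] (default 100).
#' @param n_probes,noise_sd Simulation parameters (defaults 300000 and 1).
#' @param seed Parent seed; every pair gets a derived child seed.
#' @param statistics Which statistics to compute; dropping `"qcc"` makes
#'   pure-Pearson sweeps much faster.
#' @return Data frame of class `sweep_result` with columns `snr`,
#'   `coverage`, `statistic`, `mean`, `ci_half`, `reps`, plus provenance
#'   attributes (`n_probes`, `noise_sd`, `initial_bins`, `seed`).
#' @export
coverage_sweep <- function(snr = 3, coverage = seq(0.05, 0.50, by = 0.05),
                           reps = 10, initial_bins = 100,
                           n_probes = 300000L, noise_sd = 1, seed = 1L,
                           statistics = c("pearson", "spearman", "qcc")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (reps < 2) stop_parameter("reps must be >= 2")
  grid <- expand.grid(coverage = coverage, snr = snr,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(child_seeds(seed, reps * nrow(grid)), nrow = reps)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cell <- compute_cell(n_probes, grid$coverage[i], grid$snr[i], noise_sd,
                         initial_bins, seeds[, i], statistics)
    cbind(snr = grid$snr[i], coverage = grid$coverage[i], cell)
  }))
  structure(out, class = c("sweep_result", "data.frame"),
            n_probes = n_probes, noise_sd = noise_sd,
            initial_bins = initial_bins, seed = seed)
}

#' Sweep QCC over the initial bin count
#'
#' Measures how the statistic depends on `B0`, the only tuning parameter
#' of the quantize-and-merge procedure. QCC stabilizes once the initial
#' bin count is large enough (around 100–200 for typical coverages).
#'
#' @param initial_bins Grid of `B0` values (all `>= 2`).
#' @param snr,coverage Single simulation condition for the sweep.
#' @inheritParams coverage_sweep
#' @return `sweep_result` data frame with columns `initial_bins`,
#'   `statistic`, `mean`, `ci_half`, `reps`.
#' @export
bin_sweep <- function(initial_bins = c(25, 50, 100, 200), snr = 4,
                      coverage = 0.10, reps = 10, n_probes = 300000L,
                      noise_sd = 1, seed = 1L) {
  if (reps < 2) stop_parameter("reps must be >= 2")
  if (any(initial_bins < 2)) stop_parameter("initial_bins must all be >= 2")
  if (any(initial_bins > n_probes)) {
    stop_parameter("initial_bins cannot exceed n_probes")
  }
  seeds <- matrix(child_seeds(seed, reps * length(initial_bins)),
                  nrow = reps)
  out <- do.call(rbind, lapply(seq_along(initial_bins), function(i) {
    cell <- compute_cell(n_probes, coverage, snr, noise_sd,
                         initial_bins[i], seeds[, i], "qcc")
    cbind(initial_bins = initial_bins[i], cell)
  }))
  structure(out, class = c("sweep_result", "data.frame"),
            n_probes = n_probes, noise_sd = noise_sd, snr = snr,
            coverage = coverage, seed = seed)
}

#' Simulate replicate tracks with clustered signal
#'
#' Places `n_clusters` non-overlapping runs of `cluster_size` consecutive
#' probes (default 5, ~250 bp at 50-bp spacing), each carrying mean
#' `snr * noise_sd` in both replicates; clusters are separated by at least
#' one background probe and placed uniformly at random by gap allocation
#' (no rejection). Probe order represents genomic order, so cluster
#' calling can be run directly on the output.
#'
#' @param n_probes Track length.
#' @param n_clusters Number of signal clusters (0 gives pure noise).
#' @param cluster_size Probes per cluster (default 5).
#' @param snr Signal-to-noise ratio.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return [paired_replicates()] with attributes `signal_mask` (logical)
#'   and `cluster_intervals` (data frame `start`, `end`, 1-based inclusive
#'   probe indices).
#' @export
simulate_clustered_pair <- function(n_probes, n_clusters, cluster_size = 5,
                                    snr, noise_sd = 1, seed = 1L) {
  n_probes <- as.integer(n_probes)
  n_clusters <- as.integer(n_clusters)
  cluster_size <- as.integer(cluster_size)
  if (n_clusters < 0L || cluster_size < 1L) {
    stop_parameter("n_clusters must be >= 0 and cluster_size >= 1")
  }
  if (n_clusters * (cluster_size + 1L) > n_probes) {
    stop_parameter("clusters with 1-probe gaps do not fit in n_probes")
  }
  set.seed(as.integer(seed))
  if (n_clusters > 0L) {
    # gap allocation: required space = clusters + interior 1-probe gaps;
    # distribute the free probes over the n_clusters+1 gaps uniformly
    # (stars and bars via a sorted draw without replacement)
    m <- n_clusters
    free <- n_probes - m * cluster_size - (m - 1L)
    bars <- sort(sample.int(free + m, m))
    extra <- diff(c(0L, bars)) - 1L          # extra gap before each cluster
    starts <- cumsum(extra) + (seq_len(m) - 1L) * (cluster_size + 1L) + 1L
    ends <- starts + cluster_size - 1L
    intervals <- data.frame(start = starts, end = ends)
    mask <- logical(n_probes)
    mask[unlist(Map(seq.int, starts, ends))] <- TRUE
  } else {
    intervals <- data.frame(start = integer(0), end = integer(0))
    mask <- logical(n_probes)
  }
  mu <- ifelse(mask, snr * noise_sd, 0)
  x <- mu + stats::rnorm(n_probes, sd = noise_sd)
  y <- mu + stats::rnorm(n_probes, sd = noise_sd)
  pr <- paired_replicates(x, y)
  attr(pr, "signal_mask") <- mask
  attr(pr, "cluster_intervals") <- intervals
  pr
}
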