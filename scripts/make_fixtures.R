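#!/usr/bin/env Rscript
# Regenerates the packaged synthetic fixture tracks under inst/extdata/.
# Deterministic: a fixed seed, small clustered simulation, values rounded
# to 4 decimals so the files are compact plain text.

library(quantcorr)

pr <- simulate_clustered_pair(n_probes = 400, n_clusters = 8,
                              cluster_size = 5, snr = 4, noise_sd = 1,
                              seed = 424242L)
start <- (seq_len(pr$n) - 1L) * 100L
mk <- function(values) {
  structure(data.frame(chrom = "chrS", start = start, end = start + 50L,
                       value = round(values, 4)),
            class = c("probe_track", "data.frame"))
}
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_track(mk(pr$values_x), "inst/extdata/synthetic_repA.bedgraph")
write_track(mk(pr$values_y), "inst/extdata/synthetic_repB.bedgraph")
cat("wrote", pr$n, "probes per replicate,",
    nrow(attr(pr, "cluster_intervals")), "clusters\n")
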