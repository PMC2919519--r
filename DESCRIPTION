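Package: quantcorr
Title: Quantized Correlation Coefficient for Replicate Reproducibility
    of Tiling-Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reproducibility statistics for replicate probe-level tracks
    from tiling-array experiments such as ChIP-chip. Implements the
    quantized correlation coefficient (QCC): probe signals are discretized
    into equal-count quantile bins and adjacent bins are greedily merged,
    jointly across replicates, to maximize the Pearson correlation of the
    bin labels, which suppresses the background-noise contribution that
    makes plain Pearson or Spearman correlations depend on the fraction of
    probes carrying signal. Includes a seeded simulator of replicate pairs
    (unstructured and clustered signal), parameter sweeps over signal
    coverage, signal-to-noise ratio and bin count, threshold-based cluster
    calling with a binary cluster-level concordance curve, and readers and
    writers for bedGraph and tab-delimited probe tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
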