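# quantcorr

Reproducibility statistics for replicate probe-level tracks from tiling-array
experiments (ChIP-chip and related log-ratio data).

## The problem

Replicate agreement in ChIP-chip is usually summarized by the Pearson
correlation coefficient (PCC) between probe-level log-ratios. But the PCC
confounds two things: how reproducible the signal is, and how *much* signal
there is. When only a few percent of probes carry binding signal — the common
case — the background probes, which scatter independently around zero in each
replicate, dominate the statistic and drag it down. Two experiments with
identical data quality but different binding coverage get very different
PCCs, so correlations cannot be compared across experiments.

## The statistic

The **quantized correlation coefficient (QCC)** suppresses the background
contribution without any model of the signal:

1. **Quantize.** Each replicate's values are binned into `B0` equal-count
   quantile bins (label 1 = lowest signal); probes are replaced by their bin
   label. With `B0 = n` this is the Spearman correlation's rank transform.
2. **Merge.** Of the `B − 1` ways to merge two adjacent bins (the same merge
   applied to both replicates, one shared bin structure), perform the one
   that most increases the Pearson correlation of the label vectors.
3. **Repeat** until no merge improves the correlation. The QCC is the final
   label correlation.

Background probes have labels that are independent between replicates; merging
collapses them into one large group with a single label, removing their noise
from the statistic, while reproducible signal bins stay separate. The merge
search is greedy and evaluated from the joint `B × B` contingency table of
labels, so each step costs `O(B²)` regardless of `n`, with at most
`B0(B0−1)/2` candidate evaluations in total. `B0 = 100` is a good default;
QCC is insensitive to `B0` once it is large enough.

The package also provides: a seeded simulator of replicate pairs
(`n` probes, signal coverage `p`, signal-to-noise ratio `S`, unit Gaussian
noise; unstructured or clustered signal), coverage/SNR/bin-count sweeps with
95% confidence intervals, threshold-based cluster calling (runs of ≥ 4
consecutive probes above a quantile threshold) with a binary cluster-level
concordance curve, and bedGraph/TSV track I/O.

## Worked example

Using the packaged synthetic fixture pair (400 probes, 8 clusters of 5
signal probes, SNR 4):

```r
library(quantcorr)
fa <- system.file("extdata", "synthetic_repA.bedgraph", package = "quantcorr")
fb <- system.file("extdata", "synthetic_repB.bedgraph", package = "quantcorr")
pair <- align_replicates(read_track(fa), read_track(fb))
qcc(pair, initial_bins = 40)
#> Quantized correlation coefficient
#>   probes:            400
#>   initial bins (B0): 40
#>   final bins:        4 (36 merges)
#>   Pearson (raw):     0.5835
#>   Spearman:          0.2639
#>   QCC:               0.8662
```

The raw Pearson (0.58) is held down by the 90% of probes that are pure
background; the Spearman is even lower because it weights all ranks equally.
After quantization and merging, 36 of the 40 initial bins — essentially all
of the background — have been collapsed and the QCC (0.87) reflects how well
the signal itself reproduces. The cluster-level view agrees:

```r
concordance_curve(pair, thresholds = seq(0.80, 0.98, by = 0.02))
#> concordance_curve: 10 thresholds (2 undefined); max 0.9728 at q=0.860
```

At full tiling-array scale, with 5% coverage and SNR 3 the raw PCC is ~0.30
while QCC recovers ~0.64 from the same data:

```r
pr <- simulate_replicate_pair(simulation_config(300000, 0.05, 3, seed = 1))
qcc(pr)
#>   Pearson (raw):     0.2985
#>   ...
#>   QCC:               0.6417
```

A shell entry point wrapping the same functions is installed at
`inst/cli/quantcorr.R` (subcommands `correlate`, `simulate`, `sweep`,
`clusters`).

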