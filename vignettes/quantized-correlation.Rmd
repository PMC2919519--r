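---
title: "The quantized correlation coefficient: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The quantized correlation coefficient: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantcorr)
```

## Why a quantized correlation

Probe-level reproducibility of two-color tiling-array replicates is usually
summarized by the Pearson correlation of log-ratios. The statistic is a
mixture of two contributions: signal probes, whose values co-vary between
replicates because the underlying binding is shared, and background probes,
whose values are independent noise around zero. As the fraction of probes
carrying signal (the *coverage*, `p`) shrinks, the independent background
term dominates and the correlation falls — even at constant data quality.
Under the package's simulation model this is exact: if a fraction `p` of
probes carries mean `S` (in noise-sd units) in both replicates and every
probe gets independent unit-variance noise, the population Pearson
correlation is

$$\rho(p, S) = \frac{p(1-p)S^2}{p(1-p)S^2 + 1},$$

implemented as `analytic_expected_pcc()`. At `S = 3` this moves from 0.30 at
`p = 0.05` to 0.59 at `p = 0.20`: a factor of two with no change in quality.
(The value is independent of the noise sd because `S` is expressed in
noise-sd units; scaling the noise scales the signal with it.)

The quantized correlation coefficient (QCC) removes most of this coverage
dependence. Both replicates are discretized into `B0` equal-count quantile
bins, and adjacent bins are then greedily merged — the same merge applied to
both replicates, so there is a single shared bin structure — choosing at
each step the merge that most increases the Pearson correlation of the bin
labels, until no merge improves it. Background probes occupy labels that are
independent between replicates; merging collapses them into one group whose
single label contributes nothing to the correlation's noise term, while
well-reproduced signal bins remain separate.

Because quantization uses only ranks, QCC is exactly invariant under
strictly increasing transforms of either replicate, and with one probe per
bin (`B0 = n`, no merging) the initial quantized correlation *is* the
Spearman correlation. The test suite asserts both properties exactly.

## Tunable parameters

* **`initial_bins` (`B0`)** — the only tuning parameter of the statistic
  itself. Default 100. Too few bins cannot isolate a small signal fraction
  (at 5% coverage the signal occupies the top 5 of 100 bins); beyond ~100 the
  statistic changes little. The bin sweep in the test suite (SNR 4, 10%
  coverage) shows a remaining upward drift of a few parts per thousand
  between `B0 = 100` and `B0 = 200`; it is negligible at plotting resolution
  but measurable because the Monte-Carlo standard error at 300,000 probes is
  of order 10⁻⁴. For very high SNR combined with very low coverage, raise
  `B0`.
* **Simulator parameters** — `n_probes` (default 300,000, the scale of
  high-density tiling arrays), `coverage`, `snr`, `noise_sd` (default 1;
  without loss of generality, since `snr` is in noise-sd units), `seed`.
* **Sweep replication** — `reps` simulated pairs per cell with a 95%
  confidence half-width `1.96·sd/√reps`. 100 reps gives publication-grade
  error bars; 10–30 suffices for interval-based checks because the per-pair
  standard deviation at 300,000 probes is ~10⁻³.
* **Cluster calling** — `quantile_threshold` (probes strictly above the
  empirical type-7 quantile are "high") and `min_run` (default 4 consecutive
  probes, ~150 bp at 50-bp probe spacing). `concordance_curve()` scans a
  threshold grid (default 0.80–0.995 in steps of 0.005) because a single
  "correct" threshold is unknowable without a noise model; the curve's
  maximum is the reported concordance.

## Numerical choices

* **Ties in quantization.** Equal-count blocks are formed on ranks with ties
  broken by stable input order. This guarantees bin sizes differ by at most
  one probe even in heavily tied data, at the cost of splitting tied values
  across a boundary. The alternative (keeping tied values together) would
  make bin sizes data-dependent and the contingency shortcut irregular.
* **Block boundaries.** Bin `k` spans ranks `(⌈(k−1)n/B0⌉, ⌈k·n/B0⌉]`.
* **Convergence.** "No longer improves" means no candidate exceeds the
  current correlation by more than 1e-12 (absolute); a floating-point
  plateau stops the loop rather than cycling.
* **Tie-break among merge candidates.** Candidates within 1e-12 of the best
  improvement resolve to the lowest bin index, making the procedure
  deterministic and symmetric under swapping the replicates.
* **Degenerate configurations.** A candidate that would leave zero variance
  on either margin is skipped; merging never proceeds below 2 bins; constant
  input vectors raise a typed undefined-correlation error rather than
  returning `NaN`.
* **Efficiency.** The merge search maintains the joint `B × B` label
  contingency table. Candidate correlations are computed from suffix-sum
  moment updates (O(1) per candidate after an O(B²) per-step precompute),
  and total candidate evaluations are capped at `B0(B0−1)/2` — exceeding the
  cap raises an internal error, guarding against non-termination bugs. A
  naive reference that relabels the full vectors and recomputes the
  correlation at every candidate reproduces the fast path exactly on
  randomized instances (asserted in the test suite).

## Open design choices and how they were resolved

* **Joint versus per-replicate merging.** A merge could in principle be
  applied to one replicate's bins only. The package merges the same bin pair
  in *both* replicates, keeping one shared grid of quantile cut-offs on both
  axes. This is what makes the contingency-table shortcut exact, keeps the
  statistic symmetric in its arguments, and matches the intended reading of
  a single final quantile partition separating background from signal.
* **Strict improvement.** The loop stops when the best candidate fails to
  *strictly* improve the correlation (tolerating equality could walk along
  plateaus and would make the stopping point tie-break-dependent).
* **Cluster threshold semantics.** "Above a quantile threshold" is strict
  (`>`), so a constant track calls no clusters. Cluster masks are compared
  genome-wide; callers split tracks by chromosome upstream so runs never
  span chromosomes.

## What the simulator does and does not emulate

The generator reproduces the structure that drives the coverage-dependence
phenomenon: a shared set of signal probes with a fixed mean shift, and
independent Gaussian noise per replicate. The clustered variant places
fixed-width runs (default 5 probes) separated by at least one background
probe, uniformly at random by gap allocation, so threshold-based cluster
calling behaves as it would on real enrichment tracks.

It deliberately omits: probe-sequence effects and dye bias, spatial array
artifacts, replicate-specific noise levels, biological variability in
binding position between replicates, and heavy-tailed noise. Consequently,
passing simulation-based checks demonstrates the statistic's behaviour as a
function of coverage and SNR under the stated model — not that QCC values on
real arrays equal those here. On real data the package computes the same
statistics via `read_track()`/`align_replicates()`; no acceptance claim is
tied to external datasets, which are not redistributable.

## Problem sizes used in validation

The packaged validation runs use 300,000-probe simulations with 20 seeded
pairs for the coverage-point checks, 10 replicate pairs per cell for the
coverage grid (5–50% in 5% steps) and SNR ordering, and 20 pairs per cell
for the bin-stability comparison; oracle-equivalence checks run 50 randomized
instances at `n ≤ 200`, `B0 ≤ 8`. These sizes give Monte-Carlo standard
errors at least an order of magnitude below every tolerance asserted.

## Known limitations

* QCC is a greedy local search: merged bins are never split, and a global
  search over contiguous partitions is not attempted (most merging happens
  in the background near zero, where a global search has little to gain).
* QCC is consistently higher than the raw Pearson on signal-bearing data by
  construction — it is a comparable measure across experiments, not an
  unbiased estimate of any population correlation; its maximization step can
  overcompensate.
* Residual coverage dependence remains at the very low end. In the packaged
  coverage sweep at SNR 3, the mean QCC rises noticeably between 5% and 10%
  coverage and is nearly flat from 10% to 50%; with `B0 = 100` and 5%
  coverage the signal occupies only a handful of initial bins, which limits
  how cleanly background can be separated.
* Sweeps at full array scale are embarrassingly parallel but run serially
  here; each 300,000-probe QCC evaluation takes well under a second.
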