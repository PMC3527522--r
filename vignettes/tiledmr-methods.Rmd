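---
title: "Methods: detecting cell-type DMRs on promoter tiling arrays"
author: "tiledmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting cell-type DMRs on promoter tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiledmr)
```

# The problem

MeDIP (methylated-DNA immunoprecipitation) hybridized to promoter tiling
arrays measures relative DNA methylation as probe intensity along promoters
tiled from 7.5 kb upstream to 2.45 kb downstream of each transcription start
site (TSS). Given paired samples of two cell types — epithelial and
fibroblast cells from the same donors — the goal is to find cell-type
specific differentially methylated regions (ctDMRs): contiguous stretches of
probes whose paired signal difference is consistently positive (methylated
in epithelium) or negative (methylated in fibroblasts), with calibrated
false-positive control, and then to characterize where those regions sit
relative to TSS, CpG islands and histone-modification tracks, and how they
overlap other DMR catalogs.

# The model and pipeline

## Normalization

Raw intensities are log2-transformed. On each array a smooth spatial bias
surface is estimated on the physical probe grid by a 2-D running median
(window $k \times k$, default $k = 15$, edge-truncated) and subtracted; the
array's global median is restored exactly. A running *median* is used rather
than a mean because real DMR signal occupies short runs of probes and must
not be absorbed into the surface; a 15×15 window covers 225 grid cells, so a
DMR's few dozen probes cannot dominate any window. Across arrays, quantile
normalization forces a common intensity distribution; tied values receive
the mean of the reference values over their tied ranks. That tie rule keeps
within-sample order and gives identical sorted vectors across samples
whenever the data are tie-free; with differing tie patterns across samples,
exact sorted-vector equality is unattainable by any rank-preserving method,
which the test suite acknowledges by checking the exact invariant on
continuous data only.

The stage order — log, spatial, quantile — is fixed; each stage checks the
tag of its input so the chain cannot be run out of order.

## Per-probe statistic

For probe $p$ with paired differences $d_g$ (epithelial − fibroblast, log2,
one per genotype $g = 1..n$):

$$t_p = \frac{\bar d}{\max(s_d, \varepsilon) / \sqrt n}, \qquad df = n - 1$$

with $\varepsilon = 10^{-6}$ flooring the standard deviation so
zero-variance probes (likely at $df = 2$) give $t = 0$ rather than NaN. The
genotype baseline offsets shared by each pair cancel in $d_g$, which is what
makes the paired test the right analysis for the isogenic design.

## Sliding-window score

Probes with $t$ above the global 95th percentile (below the 5th) form the
positive (negative) exceedance set. Each 300 bp window (probes whose
midpoints lie within ±150 bp of the center probe) is scored per direction
with the binomial tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n_{win}, 0.05)$,
where $k$ is the window's exceedance count. A window of 5 probes that are
all exceedances scores $0.05^5 \approx 3.1\times10^{-7}$. This is the
enrichment-of-extremes idea of the classical tiling-array window scanners,
chosen here because it is exactly reproducible from first principles; the
quantile, window width and all merging parameters are exposed as arguments.

## Calibration by position permutation

There is no per-probe multiple-testing correction; instead the window
p-value cutoff is calibrated so that the analysis as a whole controls false
positives. Each permutation shuffles the observed t-values over the fixed
probe positions — equivalent, for window statistics, to randomizing probe
positions — and reruns the scan and merging, so *every* region detected on
permuted data is a false positive. Over a descending geometric grid of
cutoffs (0.5 down to $10^{-10}$, 28 points), the chosen threshold is the
largest cutoff where

$$\widehat{\mathrm{eFDR}}(c) =
\frac{\overline{\#\,\text{null regions}(c)}}{\max(\#\,\text{observed
regions}(c), 1)} < \alpha = 0.05 .$$

A strict per-analysis false-positive-rate mode (mean null regions $<
\alpha$) is available via `mode = "fpr"`. On pure-null data the observed
and null counts track each other, so no loose cutoff passes; the
calibration then lands on a strict cutoff where both are zero and the
detector correctly reports no regions. `alpha >= 1` is treated as a vacuous
constraint (loosest cutoff), matching the intended degenerate behaviour.

Regions are merged from consecutive significant probes of the same
direction separated by at most 300 bp, and need at least 4 supporting
probes — both artifact choices (configurable), since no merging rule is
canonical. Note that the *number* of regions is not strictly monotone in
the threshold (tightening can split one long run into two valid runs); the
number of probes inside called regions is, and that is the monotonicity the
tests assert.

## Annotation and positional nulls

Each region is mapped to its nearest TSS (signed distance from the region
midpoint, negative upstream in transcript orientation, ties to the first
feature in sorted order) and nearest CpG island (edge-gap distance, 0 when
overlapping). Because array coverage is dense near TSS by design, raw
distance histograms are misleading; the positional null re-places the
observed regions (lengths preserved) with starts drawn uniformly over
probe-covered bases and rebuilds the histogram 1000 times, reporting the
per-bin mean and central 99% band. The reference point is the region
midpoint and the default bins are 250 bp over ±8 kb — both configurable,
as neither is dictated by the design. Genes whose TSS lies within 2000 bp
(inclusive) of a region midpoint form the input list for downstream
enrichment tools.

## Histone metaprofiles

Signal tracks are ingested at fixed 50 bp bins (bedGraph intervals
resampled by coverage-weighted mean). Profiles are sampled at every offset
in ±10 kb around region midpoints, averaged per direction class
(missing-aware), and smoothed with a centered 11-bin moving average;
windows are truncated at the edges. The control curve applies the same
machinery to equally many, equally long regions placed by the coverage
sampler. Tracks are unstranded, so no orientation flipping is applied.

## Overlap testing

Two region sets are partitioned by ≥1 bp overlap, evaluated per set (a set
with finer granularity can have more shared regions than its partner), with
probes covered by each partition class counted when a layout is supplied.
Significance of the shared count uses the same placement null: set A is
re-placed 5000 times while set B stays fixed, and
$p = (1 + \#\{null \ge obs\}) / (n_{iter} + 1)$. Only one set is
randomized because the null conditions on one map — the simplest null
consistent with asking "is A's coincidence with B explained by coverage?".

## CpG-unit validation statistics

Validation data are methylation fractions per (region, CpG unit, sample)
with explicit missingness. Per region, the observed unit×sample values of
the two cell types are pooled and compared with a two-sided Wilcoxon
rank-sum test — exact by enumeration of all group assignments (midranks,
so ties are handled exactly) when both classes have ≤ 10 values, normal
approximation with tie correction otherwise. Pooling across units is
deliberate: with only three samples per class, no per-sample pairing test
can reach p < 0.05. The group mean difference is computed over observed
values only. Heatmap orderings come from average-linkage clustering of
Euclidean distances on pairwise-complete values, with rows and columns
placed in canonical lexicographic order first so the result is
deterministic and invariant to input row order.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes: a
single synthetic chromosome carries one tiled block per promoter (probes
every 35 bp, 25-mers — typical promoter-tiling density, configurable since
the real platform's spacing is not asserted), three genotypes × two cell
types with genotype-shared baseline offsets (sd 0.2), a smooth per-array
spatial bias (sinusoid + Gaussian blob, amplitude 0.25 on the log2 scale),
Gaussian probe noise (default sd 0.5), and one embedded DMR in a
configurable fraction of promoters (length 300–1500 bp, log2 effect 1.0,
direction epithelial-methylated with probability 0.5). Promoters get random
strands and the tiling is mirrored for minus-strand promoters, so
TSS-relative coverage is correct in transcript coordinates. Baseline log2
intensity is 8, an unremarkable mid-scale value.

Companion generators emit one TSS per promoter, CpG islands around 60% of
TSS (±500 bp), a histone-like 50 bp track elevated by a configurable
association over epithelial-unmethylated regions, and CpG-unit validation
matrices whose group difference Δ defaults to 0.3 — mid-range of the
10–70% differences such validation experiments typically report — drawn as
truncated Gaussians clipped to [0, 1] with 5% missingness.

What a green test establishes, and what it does not: the generator draws
independent Gaussian probe noise and places DMRs independently across
promoters. Real MeDIP data have CpG-density-dependent enrichment
efficiency, correlated probe noise, copy-number artifacts and
cross-hybridization, none of which are modeled. Passing recovery tests
therefore demonstrates correctness of the pipeline's logic under its own
assumptions, not field performance on a real array.

# Numerical choices and degenerate inputs

* Variance floor $10^{-6}$ for paired t; probes with all-zero differences
  score $t = 0$.
* Calibration grid: 28 geometric points over $[10^{-10}, 0.5]$; the grid is
  an argument.
* Quantile normalization rejects missing values (the generator produces
  none); `log2_transform` rejects non-positive intensities and names the
  offending probe and sample.
* Grids smaller than the filter window fall back to a warned no-op;
  single-probe arrays pass through unchanged.
* `positional_null` and `overlap_permutation` use add-one empirical
  p-values and are deterministic given a seed; all generator functions
  derive their streams from `cfg$seed` plus fixed per-operation offsets,
  so identical configs are bit-identical regardless of call order.
* Nearest-feature ties: first feature in (chrom, position) sorted order.
* `relative_excess` rounds to the nearest integer, ties away from zero.

# Known limitations

* The window statistic assumes an approximately constant probe density
  inside a window; extremely uneven custom layouts would change the
  binomial null (the permutation calibration, however, remains valid).
* The spatial filter estimates bias on the grid actually probed; arrays
  whose grid assignment correlates perfectly with genomic position could
  absorb very long (≫ window) methylation trends into the surface.
* The empirical-FDR estimate at very strict cutoffs is a ratio of small
  counts and is reported as such, not smoothed.
* Only one set is randomized in the overlap test; if both catalogs were
  produced by correlated pipelines the p-value is anti-conservative.
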