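# tiledmr

Detection and characterization of **cell-type specific differentially
methylated regions (ctDMRs)** from MeDIP promoter tiling-array data with a
paired two-cell-type design — e.g. mammary epithelial cells (HMEC) and
fibroblasts (HMF) from the same donors.

The package is aimed at epigenomics analysts who need a fully reproducible,
permutation-calibrated sliding-window DMR caller plus the downstream
characterization steps that usually surround one: TSS / CpG-island
annotation with coverage-corrected positional nulls, histone-mark
metaprofiles with random-placement controls, DMR-set overlap permutation
tests, and validation statistics on CpG-unit (MassARRAY-style) methylation
matrices. A seeded synthetic-data generator emulates the whole experimental
design, so every stage can be exercised and tested without external data.

## The method in brief

For probe $p$, paired log2 differences $d_g$ (epithelial − fibroblast, one
per genotype) give

$$t_p = \frac{\bar d}{\max(s_d,\varepsilon)/\sqrt{n}},$$

and each 300 bp window is scored per direction with the binomial exceedance
tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n_{\mathrm{win}}, 0.05)$, where $k$
counts window probes beyond the global 95th/5th t-percentile. The window
p-value cutoff is calibrated by permutation: t-values are shuffled over the
fixed probe positions, every region found on shuffled data is a false
positive by construction, and the largest cutoff with empirical FDR
$\,\overline{N_{\mathrm{null}}}/\max(N_{\mathrm{obs}},1) < 0.05$ is used.
Significant windows of the same direction within 300 bp merge into
directional ctDMRs (≥ 4 probes).

## Worked example

```r
library(tiledmr)

cfg <- sim_config(n_promoters = 200, dmr_fraction = 0.2,
                  effect_size_log2 = 1.0, noise_sd = 0.3, seed = 7)
lay  <- generate_layout(cfg)          # 200 promoters x 285 probes
sim  <- generate_signal(cfg, lay)     # raw intensities + embedded truth
norm <- preprocess(sim$signal, lay)   # log2 -> spatial -> quantile
det  <- detect_dmrs(norm, lay, n_perm = 20, seed = 17)
det$calibration
#> calibration: cutoff 0.000292 -> 39 regions (null mean 0.25, eFDR 0.006)
#>   at efdr < 0.05 over 20 permutations
nrow(det$regions); nrow(sim$truth)
#> [1] 39
#> [1] 40
venn(det$regions, sim$truth)
#> overlap: only A = 0 | shared (A persp.) = 39 | shared (B persp.) = 39 | only B = 1
```

39 of the 40 embedded DMRs are recovered with no false calls: the
calibration chose the loosest window-p cutoff at which, across 20
permutations of probe positions, the expected number of null regions
divided by the observed count stays below 0.05 (here 0.25/39 ≈ 0.006).
Annotation and overlap testing continue from there:

```r
trk <- generate_tracks(cfg, lay, sim$truth)
ann <- nearest_tss(det$regions, trk$tss)
head(ann, 3)
#>            region_id nearest_tss_name tss_distance
#> 1   chr1:11965-12690        gene00001        -4827
#> 2 chr1:180140-181425        gene00010        -6718
#> 3 chr1:212805-213145        gene00011        -5475
length(genes_within_2kb(ann))   # gene-list input for enrichment tools
#> [1] 19
ov <- overlap_permutation(det$regions, sim$truth, lay, n_iter = 1000,
                          seed = 5)
ov$p_emp
#> [1] 0.000999001
```

The overlap p-value is the add-one empirical tail over 1000 re-placements
of the called regions across probe-covered bases — the smallest value the
test can return, as expected when A and B are the same regions.

(Printed values are the actual output of the code above; region
coordinates depend only on the seeds shown.)

## Command line

A thin CLI over the same functions ships in `inst/cli/tiledmr.R`:

```sh
Rscript inst/cli/tiledmr.R simulate --out sim/ --seed 1 --promoters 200
Rscript inst/cli/tiledmr.R detect --signal sim/signal_raw.tsv \
    --layout sim/layout.bed --sheet sim/samples.tsv --seed 1 --out dmrs.bed
Rscript inst/cli/tiledmr.R overlap --a dmrs.bed --b sim/truth.bed \
    --layout sim/layout.bed --iters 5000 --seed 1
```

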