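test_that("layout tiles each promoter at the configured density", {
  cfg <- sim_config(n_promoters = 100, seed = 3)
  lay <- generate_layout(cfg)
  # ceil((7500 + 2450) / 35) probes per promoter
  expect_equal(nrow(lay), 100 * 285)
  expect_equal(unname(table(lay$promoter)[1]), 285)

  one <- generate_layout(sim_config(n_promoters = 1, probe_spacing = 9950,
                                    seed = 3))
  expect_equal(nrow(one), 1)

  expect_error(generate_layout(sim_config(probe_spacing = 35,
                                          upstream_bp = 10,
                                          downstream_bp = 10,
                                          probe_length = 25, seed = 1)),
               "shorter than probe_length")
})

test_that("layout satisfies its structural invariants", {
  cfg <- sim_config(n_promoters = 20, seed = 5)
  lay <- generate_layout(cfg)
  expect_false(anyDuplicated(lay$probe_id) > 0)
  expect_true(all(lay$start < lay$end))
  expect_false(is.unsorted(lay$start))
  expect_true(all(lay$array_row >= 1) && all(lay$array_col >= 1))
  # every probe lies inside its promoter's tiled transcript span
  tss <- attr(lay, "tss")
  rel_lo <- ifelse(tss$strand[lay$promoter] == "+",
                   lay$start - tss$pos[lay$promoter],
                   tss$pos[lay$promoter] - lay$end)
  expect_true(all(rel_lo >= -cfg$upstream_bp))
  expect_true(all(rel_lo + cfg$probe_length <=
                    cfg$downstream_bp + cfg$probe_spacing))
})

test_that("identical config and seed give bit-identical outputs", {
  cfg <- sim_config(n_promoters = 15, dmr_fraction = 0.3, seed = 11)
  l1 <- generate_layout(cfg); l2 <- generate_layout(cfg)
  expect_identical(l1, l2)
  s1 <- generate_signal(cfg, l1); s2 <- generate_signal(cfg, l2)
  expect_identical(s1$signal$values, s2$signal$values)
  expect_identical(s1$truth, s2$truth)
  u1 <- generate_cpg_units(cfg, s1$truth)
  u2 <- generate_cpg_units(cfg, s2$truth)
  expect_identical(u1, u2)
  # a different seed changes the draw
  cfg2 <- sim_config(n_promoters = 15, dmr_fraction = 0.3, seed = 12)
  s3 <- generate_signal(cfg2, generate_layout(cfg2))
  expect_false(identical(s1$signal$values, s3$signal$values))
})

test_that("null datasets are pure: no probe has nonzero expected difference", {
  cfg <- sim_config(n_promoters = 30, dmr_fraction = 0, noise_sd = 0,
                    spatial_bias_amp = 0, seed = 2)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  expect_equal(nrow(sim$truth), 0)
  lg <- log2(sim$signal$values)
  sheet <- sim$sheet
  for (g in unique(sheet$genotype)) {
    d <- lg[, sheet$genotype == g & sheet$cell_type == "epithelial"] -
      lg[, sheet$genotype == g & sheet$cell_type == "fibroblast"]
    expect_equal(max(abs(d)), 0)
  }
})

test_that("noise-free in-DMR probes show exactly the configured effect", {
  cfg <- sim_config(n_promoters = 40, dmr_fraction = 0.5, noise_sd = 0,
                    spatial_bias_amp = 0, effect_size_log2 = 1.0, seed = 8)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  lg <- log2(sim$signal$values)
  sheet <- sim$sheet
  g <- sheet$genotype[1]
  d <- lg[, sheet$genotype == g & sheet$cell_type == "epithelial"] -
    lg[, sheet$genotype == g & sheet$cell_type == "fibroblast"]
  epi <- sim$truth[sim$truth$direction == "epithelial_methylated", ]
  in_epi <- rep(FALSE, nrow(lay))
  for (i in seq_len(nrow(epi)))
    in_epi <- in_epi | (lay$start < epi$end[i] & lay$end > epi$start[i])
  fib <- sim$truth[sim$truth$direction == "fibroblast_methylated", ]
  in_fib <- rep(FALSE, nrow(lay))
  for (i in seq_len(nrow(fib)))
    in_fib <- in_fib | (lay$start < fib$end[i] & lay$end > fib$start[i])
  expect_true(all(d[in_epi & !in_fib] == 1.0))
  expect_true(all(d[in_fib & !in_epi] == -1.0))
  expect_true(all(d[!in_epi & !in_fib] == 0))
})

test_that("mean in-DMR paired difference matches the effect size under noise", {
  cfg <- sim_config(n_promoters = 500, dmr_fraction = 0.2, noise_sd = 0.5,
                    spatial_bias_amp = 0, effect_size_log2 = 1.0,
                    direction_prob = 1, seed = 21)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  lg <- log2(sim$signal$values)
  sheet <- sim$sheet
  in_dmr <- rep(FALSE, nrow(lay))
  for (i in seq_len(nrow(sim$truth)))
    in_dmr <- in_dmr | (lay$start < sim$truth$end[i] &
                          lay$end > sim$truth$start[i])
  d <- numeric(0)
  for (g in unique(sheet$genotype)) {
    d <- c(d, lg[in_dmr, sheet$genotype == g & sheet$cell_type == "epithelial"] -
             lg[in_dmr, sheet$genotype == g & sheet$cell_type == "fibroblast"])
  }
  # CLT: each paired difference has sd sqrt(2) * noise_sd
  se <- sqrt(2) * cfg$noise_sd / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.0), 1.96 * se * 2)
})

test_that("tracks and annotations reflect the configured association", {
  cfg <- sim_config(n_promoters = 50, dmr_fraction = 0.4, seed = 31)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  trk <- generate_tracks(cfg, lay, sim$truth, association = 2,
                         track_noise_sd = 0)
  expect_equal(nrow(trk$tss), 50)
  # noise-free maximal association: track mean over
  # epithelial-unmethylated regions is base + association exactly
  fib <- sim$truth[sim$truth$direction == "fibroblast_methylated", ]
  epi <- sim$truth[sim$truth$direction == "epithelial_methylated", ]
  v_fib <- track_value(trk$track, "chr1", region_midpoint(fib))
  v_epi <- track_value(trk$track, "chr1", region_midpoint(epi))
  expect_true(all(v_fib == 3))
  expect_true(all(v_epi == 1))

  # association 0: track independent of truth labels
  trk0 <- generate_tracks(cfg, lay, sim$truth, association = 0,
                          track_noise_sd = 0.1)
  v0 <- track_value(trk0$track, "chr1", region_midpoint(sim$truth))
  expect_lt(abs(mean(v0[sim$truth$direction == "fibroblast_methylated"]) -
                  mean(v0[sim$truth$direction == "epithelial_methylated"])),
            0.2)

  one <- sim_config(n_promoters = 1, seed = 31)
  lay1 <- generate_layout(one)
  trk1 <- generate_tracks(one, lay1,
                          data.frame(chrom = character(), start = integer(),
                                     end = integer(), direction = character()))
  expect_equal(nrow(trk1$tss), 1)
})

test_that("CpG-unit generator hits the configured group difference", {
  cfg <- sim_config(n_promoters = 30, dmr_fraction = 0.5, seed = 41)
  lay <- generate_layout(cfg)
  truth <- generate_signal(cfg, lay)$truth

  # delta 0, noise 0: group means exactly equal
  u0 <- generate_cpg_units(cfg, truth, delta = 0, noise_sd = 0,
                           missing_rate = 0)
  r0 <- region_tests(u0)
  expect_true(all(r0$mean_diff == 0))

  # delta 0.10, noise 0: per-region mean difference exactly +/- 0.10
  u <- generate_cpg_units(cfg, truth, delta = 0.10, noise_sd = 0,
                          missing_rate = 0)
  r <- region_tests(u)
  expect_true(all(abs(abs(r$mean_diff) - 0.10) < 1e-12))

  # full missingness: downstream statistics flag insufficient data
  um <- generate_cpg_units(cfg, truth, missing_rate = 1)
  expect_true(all(is.na(um$fraction)))
  rm <- region_tests(um)
  expect_true(all(!rm$sufficient))
  expect_true(all(is.na(rm$p)))
})
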