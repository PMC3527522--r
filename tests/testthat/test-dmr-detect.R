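test_that("paired t matches the closed form and handles degenerate probes", {
  lay <- tiny_layout(c(0, 1000))
  m <- diff_signal(c(1.0, 1.2, 0.8), lay)
  res <- paired_t(m)
  # d = (1.0, 1.2, 0.8): mean 1, sd 0.2, t = 1 / (0.2 / sqrt(3))
  expect_equal(res$t, rep(8.6602540378, 2), tolerance = 1e-9)
  expect_equal(res$d_mean, rep(1, 2))
  expect_equal(res$df, rep(2L, 2))

  m0 <- diff_signal(c(0, 0, 0), lay)
  expect_equal(paired_t(m0)$t, c(0, 0))

  # sign(t) always matches sign(d_mean)
  set.seed(1)
  mr <- diff_signal(rnorm(3), tiny_layout(0))
  r <- paired_t(mr)
  expect_true(all(sign(r$t) == sign(r$d_mean)))
})

test_that("swapping cell-type labels negates t exactly", {
  set.seed(7)
  lay <- tiny_layout(seq(0, 35 * 49, 35))
  sheet <- tiny_sheet(3)
  vals <- matrix(rnorm(50 * 6, 8), 50, 6,
                 dimnames = list(lay$probe_id, sheet$sample_id))
  m <- signal_matrix(vals, lay, sheet, stage = "raw"); m$stage <- "quantile"
  swapped <- sheet
  swapped$cell_type <- ifelse(sheet$cell_type == "epithelial",
                              "fibroblast", "epithelial")
  expect_equal(paired_t(m, swapped)$t, -paired_t(m, sheet)$t)
})

test_that("unpaired sample sheets are rejected", {
  lay <- tiny_layout(c(0, 100))
  sheet <- tiny_sheet(2)
  sheet$genotype[2] <- "g9"   # breaks the pairing
  vals <- matrix(1, 2, 4, dimnames = list(lay$probe_id, sheet$sample_id))
  m <- signal_matrix(vals, lay, sheet, stage = "raw"); m$stage <- "quantile"
  expect_error(paired_t(m, sheet), "not paired")
})

test_that("window scan reproduces the binomial tail", {
  # 5 clustered probes carry the top-5 t of 100; the rest are isolated
  pos <- c(seq(0, 60, by = 15), seq(10000, 10000 + 2000 * 94, by = 2000))
  lay <- tiny_layout(pos, len = 10L)
  tt <- c(rep(10, 5), rep(0, 95))
  ts <- data.frame(probe_id = lay$probe_id, t = tt, d_mean = tt, df = 2L)
  class(ts) <- c("tstat_track", "data.frame")
  sc <- window_scan(ts, lay, window_bp = 300, q = 0.95)
  clustered <- sc$pos < 1000
  expect_equal(sc$n_window[clustered], rep(5L, 5))
  expect_equal(sc$k_pos[clustered], rep(5L, 5))
  # P(X >= 5), X ~ Bin(5, 0.05): 0.05^5
  expect_equal(sc$p_pos[clustered], rep(3.125e-7, 5), tolerance = 1e-12)
  # windows with no exceedance: p = P(X >= 0) = 1
  expect_true(all(sc$p_pos[!clustered] == 1))
  expect_true(all(sc$p_neg == 1))
})

test_that("window p-values are calibrated under a uniform null", {
  # isolated probes -> singleton decorrelated windows
  set.seed(123)
  n <- 4000
  lay <- tiny_layout(seq(0, 2000 * (n - 1), by = 2000), len = 10L)
  ts <- data.frame(probe_id = lay$probe_id, t = rnorm(n),
                   d_mean = 0, df = 2L)
  class(ts) <- c("tstat_track", "data.frame")
  sc <- window_scan(ts, lay, q = 0.95)
  alpha <- 0.0501
  frac <- mean(sc$p_pos < alpha)
  expect_lte(frac, alpha + 3 * sqrt(alpha / n))
})

test_that("region calling merges runs and respects direction and min_probes", {
  pos <- seq(0, 35 * 29, by = 35)
  lay <- tiny_layout(pos, len = 25L)
  p_pos <- rep(1, 30); p_pos[10:15] <- 1e-6   # one run of 6
  sc <- data.frame(probe_id = lay$probe_id, chrom = "chr1", pos = pos,
                   n_window = 9L, k_pos = 0L, k_neg = 0L,
                   p_pos = p_pos, p_neg = 1)
  class(sc) <- c("window_score", "data.frame")
  reg <- call_regions(sc, lay, threshold_p = 1e-3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$direction, "epithelial_methylated")
  expect_equal(reg$n_probes, 6L)
  expect_equal(reg$start, lay$start[10])
  expect_equal(reg$end, lay$end[15])
  expect_equal(reg$best_p, 1e-6)

  # nothing below threshold -> empty
  expect_equal(nrow(call_regions(sc, lay, threshold_p = 1e-7)), 0)
  # run shorter than min_probes -> dropped
  expect_equal(nrow(call_regions(sc, lay, threshold_p = 1e-3,
                                 min_probes = 7)), 0)
  # negative direction mirrors
  sc2 <- sc; sc2$p_neg <- sc$p_pos; sc2$p_pos <- 1
  reg2 <- call_regions(sc2, lay, threshold_p = 1e-3)
  expect_equal(reg2$direction, "fibroblast_methylated")
  expect_equal(reg2[c("start", "end", "n_probes")],
               reg[c("start", "end", "n_probes")])
})

test_that("probe support of called regions is monotone in the threshold", {
  cfg <- sim_config(n_promoters = 60, dmr_fraction = 0.2, noise_sd = 0.4,
                    spatial_bias_amp = 0, seed = 77)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  m <- log2_transform(sim$signal); m$stage <- "quantile"
  sc <- window_scan(paired_t(m), lay)
  cuts <- 10^seq(-1, -8, length.out = 12)
  probes <- vapply(cuts, function(th)
    sum(call_regions(sc, lay, th)$n_probes), numeric(1))
  expect_true(all(diff(probes) <= 0))
})

test_that("calibration reports no regions on pure-null data", {
  cfg <- sim_config(n_promoters = 150, dmr_fraction = 0, noise_sd = 0.5,
                    spatial_bias_amp = 0, seed = 5)
  lay <- generate_layout(cfg)
  m <- log2_transform(generate_signal(cfg, lay)$signal)
  m$stage <- "quantile"
  tstat <- paired_t(m)
  cal <- calibrate_threshold(tstat, lay, n_perm = 10, seed = 9)
  sc <- window_scan(tstat, lay)
  reg <- call_regions(sc, lay, cal$threshold_p)
  expect_equal(nrow(reg), 0)
  if (!is.na(cal$efdr)) expect_lt(cal$efdr, 0.05)
})

test_that("calibration finds a cutoff on strong signal and recovers truth", {
  cfg <- sim_config(n_promoters = 150, dmr_fraction = 0.2,
                    effect_size_log2 = 1.0, noise_sd = 0.3, seed = 42)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  norm <- preprocess(sim$signal, lay)
  det <- detect_dmrs(norm, lay, n_perm = 10, seed = 3)
  expect_false(is.na(det$calibration$threshold_p))
  expect_lt(det$calibration$efdr, 0.05)

  # sensitivity >= 90%, direction correctness 100% among recovered
  truth <- sim$truth
  hit_dir <- vapply(seq_len(nrow(truth)), function(i) {
    ov <- det$regions$chrom == truth$chrom[i] &
      det$regions$start < truth$end[i] & det$regions$end > truth$start[i]
    if (!any(ov)) NA_character_ else
      paste(unique(det$regions$direction[ov]), collapse = ",")
  }, character(1))
  sens <- mean(!is.na(hit_dir))
  expect_gte(sens, 0.9)
  expect_true(all(hit_dir[!is.na(hit_dir)] == truth$direction[!is.na(hit_dir)]))
})

test_that("alpha = 1 returns the loosest cutoff on the grid", {
  set.seed(2)
  lay <- tiny_layout(seq(0, 35 * 199, 35))
  ts <- data.frame(probe_id = lay$probe_id, t = rnorm(200), d_mean = 0,
                   df = 2L)
  class(ts) <- c("tstat_track", "data.frame")
  grid <- c(0.5, 0.05, 0.005)
  cal <- calibrate_threshold(ts, lay, alpha = 1.0, n_perm = 2, grid = grid,
                             seed = 1)
  expect_equal(cal$threshold_p, 0.5)
  expect_error(calibrate_threshold(ts, lay, n_perm = 0), "n_perm")
})

test_that("label swap maps regions onto the mirrored directions", {
  cfg <- sim_config(n_promoters = 80, dmr_fraction = 0.25,
                    effect_size_log2 = 1, noise_sd = 0.3, seed = 55)
  lay <- generate_layout(cfg)
  sim <- generate_signal(cfg, lay)
  m <- log2_transform(sim$signal); m$stage <- "quantile"
  sheet <- sim$sheet
  swapped <- sheet
  swapped$cell_type <- ifelse(sheet$cell_type == "epithelial",
                              "fibroblast", "epithelial")
  th <- 1e-4
  r1 <- call_regions(window_scan(paired_t(m, sheet), lay), lay, th)
  r2 <- call_regions(window_scan(paired_t(m, swapped), lay), lay, th)
  expect_gt(nrow(r1), 0)
  flip <- c(epithelial_methylated = "fibroblast_methylated",
            fibroblast_methylated = "epithelial_methylated")
  r2m <- r2[order(r2$start), ]
  r1m <- r1[order(r1$start), ]
  expect_equal(r1m[c("chrom", "start", "end", "n_probes")],
               r2m[c("chrom", "start", "end", "n_probes")])
  expect_equal(unname(flip[r1m$direction]), r2m$direction)
})
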