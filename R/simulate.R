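#' Simulation configuration for synthetic promoter tiling-array data
#'
#' Describes a synthetic MeDIP tiling-array experiment with the structure the
#' downstream analysis assumes: promoters tiled from `upstream_bp` before to
#' `downstream_bp` after each TSS, a paired design with `n_genotypes` donors
#' contributing one epithelial and one fibroblast sample each, a fraction of
#' promoters carrying one embedded directional DMR, smooth spatial bias on
#' the physical array grid, and Gaussian probe noise on the log2 scale.
#'
#' @param n_promoters number of tiled promoters.
#' @param upstream_bp,downstream_bp promoter span relative to the TSS
#'   (defaults 7500 and 2450 bp, the span of the promoter array emulated).
#' @param probe_spacing probe start-to-start distance in bp.
#' @param probe_length probe length in bp.
#' @param n_genotypes number of donors (genotype pairs).
#' @param dmr_fraction fraction of promoters carrying one embedded DMR.
#' @param dmr_length_range length range (bp) DMR lengths are drawn from.
#' @param effect_size_log2 mean log2 intensity shift added to the methylated
#'   cell type inside a DMR.
#' @param direction_prob probability an embedded DMR is epithelial-methylated.
#' @param noise_sd standard deviation of Gaussian probe noise (log2 scale).
#' @param spatial_bias_amp amplitude of the smooth per-array 2-D bias surface
#'   (log2 scale); 0 disables spatial bias.
#' @param baseline_log2 grand mean log2 intensity.
#' @param genotype_sd standard deviation of per-genotype baseline offsets
#'   (shared by the two samples of a pair, which is what makes the paired
#'   t-test the correct analysis).
#' @param promoter_gap_bp unprobed gap between consecutive promoter blocks.
#' @param seed integer seed; identical config and seed give bit-identical
#'   output from every generator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_promoters = 500,
                       upstream_bp = 7500, downstream_bp = 2450,
                       probe_spacing = 35, probe_length = 25,
                       n_genotypes = 3,
                       dmr_fraction = 0.1,
                       dmr_length_range = c(300, 1500),
                       effect_size_log2 = 1.0,
                       direction_prob = 0.5,
                       noise_sd = 0.5,
                       spatial_bias_amp = 0.25,
                       baseline_log2 = 8,
                       genotype_sd = 0.2,
                       promoter_gap_bp = 5000,
                       seed = 1L) {
  cfg <- list(
    n_promoters = as.integer(n_promoters),
    upstream_bp = as.integer(upstream_bp),
    downstream_bp = as.integer(downstream_bp),
    probe_spacing = as.integer(probe_spacing),
    probe_length = as.integer(probe_length),
    n_genotypes = as.integer(n_genotypes),
    dmr_fraction = dmr_fraction,
    dmr_length_range = as.integer(dmr_length_range),
    effect_size_log2 = effect_size_log2,
    direction_prob = direction_prob,
    noise_sd = noise_sd,
    spatial_bias_amp = spatial_bias_amp,
    baseline_log2 = baseline_log2,
    genotype_sd = genotype_sd,
    promoter_gap_bp = as.integer(promoter_gap_bp),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_promoters > 0, cfg$n_genotypes > 0,
    cfg$upstream_bp >= 0, cfg$downstream_bp >= 0,
    cfg$probe_spacing > 0, cfg$probe_length > 0,
    cfg$dmr_fraction >= 0, cfg$dmr_fraction <= 1,
    length(cfg$dmr_length_range) == 2,
    cfg$dmr_length_range[1] <= cfg$dmr_length_range[2],
    cfg$noise_sd >= 0, cfg$spatial_bias_amp >= 0,
    cfg$direction_prob >= 0, cfg$direction_prob <= 1,
    cfg$promoter_gap_bp >= 0
  )
  structure(cfg, class = "sim_config")
}

#' Paired sample sheet for a simulated experiment
#'
#' One epithelial and one fibroblast sample per genotype. With three
#' genotypes the donor labels mirror a typical isogenic strain-pair design.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `sample_id`, `genotype`, `cell_type`.
#' @export
sample_sheet <- function(cfg) {
  genos <- if (cfg$n_genotypes == 3) c("184", "48", "240") else
    paste0("g", seq_len(cfg$n_genotypes))
  data.frame(
    sample_id = paste0(rep(genos, each = 2), "_",
                       rep(c("epi", "fib"), cfg$n_genotypes)),
    genotype  = rep(genos, each = 2),
    cell_type = rep(c("epithelial", "fibroblast"), cfg$n_genotypes),
    stringsAsFactors = FALSE
  )
}

#' Generate the probe layout of the simulated tiling array
#'
#' Each promoter occupies its own genomic block on a single synthetic
#' chromosome; probes tile the span from `upstream_bp` before to
#' `downstream_bp` after the TSS at `probe_spacing` resolution, mirrored for
#' minus-strand promoters so the tiling is symmetric in transcript
#' coordinates. Physical grid positions (`array_row`, `array_col`) are
#' assigned in row-major order over a near-square grid, a deterministic
#' space-filling order.
#'
#' @param cfg a [sim_config()].
#' @return data.frame of class `probe_layout` with columns `probe_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `array_row`, `array_col`,
#'   `promoter`; the promoter/TSS table is attached as attribute `"tss"`.
#' @export
generate_layout <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  span <- cfg$upstream_bp + cfg$downstream_bp
  if (span < cfg$probe_length)
    stop("promoter span (", span, " bp) is shorter than probe_length (",
         cfg$probe_length, " bp)", call. = FALSE)
  n_pp <- as.integer(ceiling(span / cfg$probe_spacing))
  half <- max(cfg$upstream_bp, cfg$downstream_bp)
  stride <- 2L * half + cfg$promoter_gap_bp

  with_seed(cfg$seed + 11L, {
    strand <- sample(c("+", "-"), cfg$n_promoters, replace = TRUE)
    tss_pos <- half + (seq_len(cfg$n_promoters) - 1L) * stride

    rel <- -cfg$upstream_bp + (seq_len(n_pp) - 1L) * cfg$probe_spacing
    pid <- sprintf("p%05d_%04d", rep(seq_len(cfg$n_promoters), each = n_pp),
                   rep(seq_len(n_pp), cfg$n_promoters))
    tss_rep <- rep(tss_pos, each = n_pp)
    str_rep <- rep(strand, each = n_pp)
    rel_rep <- rep(rel, cfg$n_promoters)
    start <- ifelse(str_rep == "+",
                    tss_rep + rel_rep,
                    tss_rep - rel_rep - cfg$probe_length)
    layout <- data.frame(
      probe_id  = pid,
      chrom     = "chr1",
      start     = as.integer(start),
      end       = as.integer(start) + cfg$probe_length,
      promoter  = rep(seq_len(cfg$n_promoters), each = n_pp),
      stringsAsFactors = FALSE
    )
    layout <- layout[order(layout$chrom, layout$start, layout$probe_id), ]
    rownames(layout) <- NULL
    n <- nrow(layout)
    ncol_grid <- as.integer(ceiling(sqrt(n)))
    idx <- seq_len(n) - 1L
    layout$array_row <- idx %/% ncol_grid + 1L
    layout$array_col <- idx %% ncol_grid + 1L
    attr(layout, "tss") <- data.frame(
      promoter = seq_len(cfg$n_promoters),
      chrom = "chr1",
      pos = as.integer(tss_pos),
      strand = strand,
      name = sprintf("gene%05d", seq_len(cfg$n_promoters)),
      stringsAsFactors = FALSE
    )
    attr(layout, "config") <- cfg
    class(layout) <- c("probe_layout", "data.frame")
    layout
  })
}

## Smooth per-array bias surface on the grid: a low-frequency sinusoid plus
## a Gaussian blob, both with per-array random phase/position.
spatial_bias_surface <- function(nr, nc, amp) {
  if (amp == 0) return(matrix(0, nr, nc))
  ph1 <- runif(1); ph2 <- runif(1)
  r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc)
  sg <- 0.25 * max(nr, nc)
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sine <- sin(2 * pi * (1.5 * r / nr + ph1)) * cos(2 * pi * (1.5 * cc / nc + ph2))
  blob <- exp(-((r - r0)^2 + (cc - c0)^2) / (2 * sg^2))
  amp * (0.6 * sine + 0.8 * blob)
}

#' Generate raw probe intensities and the embedded-DMR truth set
#'
#' Log2 signal for probe p on the sample of genotype g and cell type c is
#' `baseline + offset_g + bias_array(row, col) + delta * 1[p in a DMR
#' methylated in c] + N(0, noise_sd)`; raw intensity is 2 to that power.
#' Genotype offsets are shared within a pair, so paired differences cancel
#' them exactly.
#'
#' @param cfg a [sim_config()].
#' @param layout a [generate_layout()] result for the same config.
#' @return list with elements `signal` (a `signal_matrix`, stage `"raw"`),
#'   `truth` (data.frame `chrom`, `start`, `end`, `direction`), and `sheet`.
#' @export
generate_signal <- function(cfg, layout) {
  stopifnot(inherits(cfg, "sim_config"), inherits(layout, "probe_layout"))
  sheet <- sample_sheet(cfg)
  tss <- attr(layout, "tss")
  n <- nrow(layout)

  with_seed(cfg$seed + 23L, {
    ## embedded truth DMRs, placed within the tiled transcript span
    n_dmr <- round(cfg$dmr_fraction * cfg$n_promoters)
    if (n_dmr > 0) {
      which_prom <- sort(sample.int(cfg$n_promoters, n_dmr))
      len <- as.integer(round(runif(n_dmr, cfg$dmr_length_range[1],
                                    cfg$dmr_length_range[2])))
      span <- cfg$upstream_bp + cfg$downstream_bp
      len <- pmin(len, span)
      rel_start <- as.integer(floor(runif(n_dmr) *
                                    (span - len + 1))) - cfg$upstream_bp
      str <- tss$strand[which_prom]
      pos <- tss$pos[which_prom]
      g_start <- ifelse(str == "+", pos + rel_start, pos - rel_start - len)
      direction <- ifelse(runif(n_dmr) < cfg$direction_prob,
                          "epithelial_methylated", "fibroblast_methylated")
      truth <- data.frame(
        chrom = "chr1",
        start = as.integer(g_start),
        end   = as.integer(g_start) + len,
        direction = direction,
        promoter = which_prom,
        stringsAsFactors = FALSE
      )
      truth <- truth[order(truth$start), ]
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          promoter = integer(), stringsAsFactors = FALSE)
    }

    ## per-probe DMR membership (any overlap), by direction
    in_dir <- matrix(FALSE, n, 2,
                     dimnames = list(NULL, c("epithelial_methylated",
                                             "fibroblast_methylated")))
    if (nrow(truth)) {
      hit <- GenomicRanges::findOverlaps(as_granges0(layout[c("chrom", "start", "end")]),
                                         as_granges0(truth[c("chrom", "start", "end")]))
      qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
      in_dir[cbind(qh, match(truth$direction[sh], colnames(in_dir)))] <- TRUE
    }

    geno_off <- rnorm(cfg$n_genotypes, 0, cfg$genotype_sd)
    names(geno_off) <- unique(sheet$genotype)
    nr <- max(layout$array_row); nc <- max(layout$array_col)
    grid_idx <- cbind(layout$array_row, layout$array_col)

    vals <- matrix(NA_real_, n, nrow(sheet),
                   dimnames = list(layout$probe_id, sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
      ct <- sheet$cell_type[j]
      dir_col <- if (ct == "epithelial") "epithelial_methylated" else
        "fibroblast_methylated"
      bias <- spatial_bias_surface(nr, nc, cfg$spatial_bias_amp)
      lg <- cfg$baseline_log2 + geno_off[sheet$genotype[j]] +
        bias[grid_idx] +
        cfg$effect_size_log2 * in_dir[, dir_col] +
        (if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0)
      vals[, j] <- 2^lg
    }

    list(
      signal = signal_matrix(vals, layout, sheet, stage = "raw"),
      truth  = truth,
      sheet  = sheet
    )
  })
}

#' Construct a signal_matrix container
#'
#' Probes-by-samples intensity matrix aligned to a probe layout, tagged with
#' its processing stage (`raw`, `logged`, `spatial`, `quantile`).
#'
#' @param values numeric matrix, rows in layout order, columns per sample.
#' @param layout the probe layout the rows align to.
#' @param sheet the sample sheet the columns align to.
#' @param stage processing stage tag.
#' @return object of class `signal_matrix`.
#' @export
signal_matrix <- function(values, layout, sheet,
                          stage = c("raw", "logged", "spatial", "quantile")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), nrow(values) == nrow(layout),
            ncol(values) == nrow(sheet))
  structure(list(values = values, probe_ids = layout$probe_id,
                 sheet = sheet, stage = stage),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples, stage =", x$stage, "\n")
  invisible(x)
}

#' Generate annotation tables and histone-like signal tracks
#'
#' Emits one TSS per promoter, CpG islands around a configurable fraction of
#' TSS, and a fixed-step histone-like enrichment track whose signal is
#' elevated over truth regions that are unmethylated in epithelium
#' (fibroblast-methylated), emulating the association of permissive histone
#' marks with epithelial hypomethylation. `association = 0` makes the track
#' independent of the truth labels.
#'
#' @param cfg a [sim_config()].
#' @param layout a [generate_layout()] result.
#' @param truth truth-set data.frame from [generate_signal()].
#' @param association enrichment added over epithelial-unmethylated regions.
#' @param track_noise_sd Gaussian noise sd of the track values.
#' @param island_fraction fraction of TSS flanked by a CpG island.
#' @param island_halfwidth island half-width in bp around the TSS.
#' @param step track bin width in bp.
#' @return list with `tss` and `islands` feature tables and `track`
#'   (a `genomic_track`).
#' @export
generate_tracks <- function(cfg, layout, truth,
                            association = 1.0, track_noise_sd = 0.1,
                            island_fraction = 0.6, island_halfwidth = 500L,
                            step = 50L) {
  stopifnot(inherits(layout, "probe_layout"))
  tss <- attr(layout, "tss")
  with_seed(cfg$seed + 37L, {
    n_isl <- round(island_fraction * nrow(tss))
    isl_prom <- sort(sample.int(nrow(tss), n_isl))
    islands <- data.frame(
      chrom = tss$chrom[isl_prom],
      start = pmax(0L, tss$pos[isl_prom] - as.integer(island_halfwidth)),
      end   = tss$pos[isl_prom] + as.integer(island_halfwidth),
      name  = sprintf("CpG_%05d", seq_along(isl_prom)),
      stringsAsFactors = FALSE
    )

    chrom_end <- max(layout$end) + 20000L
    nbin <- as.integer(ceiling(chrom_end / step))
    vals <- 1 + (if (track_noise_sd > 0) rnorm(nbin, 0, track_noise_sd) else
      numeric(nbin))
    hypo <- truth[truth$direction == "fibroblast_methylated", , drop = FALSE]
    if (nrow(hypo) && association != 0) {
      for (i in seq_len(nrow(hypo))) {
        b0 <- hypo$start[i] %/% step + 1L
        b1 <- min(nbin, (hypo$end[i] - 1L) %/% step + 1L)
        vals[b0:b1] <- vals[b0:b1] + association
      }
    }
    track <- genomic_track(list(chr1 = vals), step = as.integer(step))
    list(tss = tss[c("chrom", "pos", "strand", "name")],
         islands = islands, track = track)
  })
}

#' Generate a CpG-unit methylation matrix for validation regions
#'
#' For each truth region, each CpG unit and each sample, a methylation
#' fraction is drawn as a Gaussian around the cell-type mean and clipped to
#' [0, 1] (a truncated-Gaussian stand-in for beta-like noise). The
#' methylated cell type's mean sits `delta` above `base_level`. A fraction
#' of entries is set missing, emulating mass-spectrometry quality dropouts.
#'
#' @param cfg a [sim_config()].
#' @param truth truth-set data.frame (regions to validate).
#' @param sheet sample sheet; defaults to [sample_sheet()] of `cfg`.
#' @param n_units CpG units per region.
#' @param base_level methylation fraction of the unmethylated cell type.
#' @param delta mean group difference in methylation fraction.
#' @param noise_sd Gaussian noise sd before clipping; 0 gives exact means.
#' @param missing_rate probability an entry is missing.
#' @return long-format data.frame of class `cpg_unit_matrix` with columns
#'   `region_id`, `unit_id`, `sample_id`, `cell_type`, `fraction` (NA when
#'   missing).
#' @export
generate_cpg_units <- function(cfg, truth, sheet = sample_sheet(cfg),
                               n_units = 8, base_level = 0.25, delta = 0.3,
                               noise_sd = 0.05, missing_rate = 0.05) {
  stopifnot(delta >= 0, base_level + delta <= 1, missing_rate >= 0,
            missing_rate <= 1)
  nr <- nrow(truth)
  if (nr == 0) {
    out <- data.frame(region_id = character(), unit_id = character(),
                      sample_id = character(), cell_type = character(),
                      fraction = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("cpg_unit_matrix", "data.frame")
    return(out)
  }
  region_id <- sprintf("%s:%d-%d", truth$chrom, truth$start, truth$end)
  with_seed(cfg$seed + 53L, {
    grid <- expand.grid(unit = seq_len(n_units), region = seq_len(nr),
                        samp = seq_len(nrow(sheet)))
    meth_ct <- ifelse(truth$direction[grid$region] == "epithelial_methylated",
                      "epithelial", "fibroblast")
    mu <- base_level + delta * (sheet$cell_type[grid$samp] == meth_ct)
    x <- mu + (if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0)
    x <- pmin(1, pmax(0, x))
    if (missing_rate > 0) x[runif(nrow(grid)) < missing_rate] <- NA_real_
    out <- data.frame(
      region_id = region_id[grid$region],
      unit_id   = sprintf("u%02d", grid$unit),
      sample_id = sheet$sample_id[grid$samp],
      cell_type = sheet$cell_type[grid$samp],
      fraction  = x,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cpg_unit_matrix", "data.frame")
    out
  })
}
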