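#' Per-probe paired t-statistics
#'
#' For each probe, paired differences d_g = epithelial_g - fibroblast_g are
#' taken across genotypes and t = mean(d) / (sd(d) / sqrt(n)). The standard
#' deviation is floored at `var_floor` so zero-variance probes give finite
#' statistics (a probe with all-zero differences gets t = 0).
#'
#' @param m a `signal_matrix` (normally stage `"quantile"`).
#' @param sheet paired sample sheet: each genotype must appear exactly once
#'   per cell type.
#' @param var_floor lower bound on sd(d).
#' @return data.frame of class `tstat_track` with columns `probe_id`, `t`,
#'   `d_mean`, `df`.
#' @export
paired_t <- function(m, sheet = m$sheet, var_floor = 1e-6) {
  stopifnot(inherits(m, "signal_matrix"))
  tab <- table(sheet$genotype, sheet$cell_type)
  if (!all(dim(tab) == c(length(unique(sheet$genotype)), 2)) ||
      !all(tab == 1))
    stop("sample sheet is not paired: each genotype must appear exactly ",
         "once per cell type", call. = FALSE)
  genos <- unique(sheet$genotype)
  if (length(genos) < 2) stop("need at least 2 complete genotype pairs")
  epi <- vapply(genos, function(g)
    sheet$sample_id[sheet$genotype == g & sheet$cell_type == "epithelial"], "")
  fib <- vapply(genos, function(g)
    sheet$sample_id[sheet$genotype == g & sheet$cell_type == "fibroblast"], "")
  d <- m$values[, epi, drop = FALSE] - m$values[, fib, drop = FALSE]
  n <- length(genos)
  d_mean <- rowMeans(d)
  s <- sqrt(rowSums((d - d_mean)^2) / (n - 1))
  t <- d_mean / (pmax(s, var_floor) / sqrt(n))
  out <- data.frame(probe_id = m$probe_ids, t = t, d_mean = d_mean,
                    df = n - 1L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tstat_track", "data.frame")
  out
}

#' Sliding-window enrichment scan of the t-statistic profile
#'
#' Probes whose t-statistic exceeds the global `q` quantile (or falls below
#' the `1 - q` quantile) form the positive (negative) exceedance set. For
#' each probe, the window of probes whose midpoints lie within
#' `window_bp / 2` of its midpoint is scored in each direction with the
#' binomial tail P(X >= k), X ~ Bin(n_window, 1 - q), where k is the number
#' of exceedances in the window.
#'
#' @param tstat a `tstat_track` from [paired_t()].
#' @param layout probe layout (defines positions; probes sorted by position
#'   per chromosome).
#' @param window_bp window width in bp (default 300).
#' @param q exceedance quantile (default 0.95).
#' @return data.frame of class `window_score` with per-probe columns
#'   `probe_id`, `chrom`, `pos`, `n_window`, `k_pos`, `k_neg`, `p_pos`,
#'   `p_neg`.
#' @export
window_scan <- function(tstat, layout, window_bp = 300, q = 0.95) {
  stopifnot(nrow(tstat) == nrow(layout),
            all(tstat$probe_id == layout$probe_id))
  tt <- tstat$t
  up <- stats::quantile(tt, q, names = FALSE)
  lo <- stats::quantile(tt, 1 - q, names = FALSE)
  e_pos <- tt > up
  e_neg <- tt < lo
  pos <- region_midpoint(layout)
  half <- window_bp / 2
  n <- length(pos)
  n_window <- integer(n); k_pos <- integer(n); k_neg <- integer(n)
  for (ch in unique(layout$chrom)) {
    sel <- which(layout$chrom == ch)
    if (!length(sel)) {
      warning("chromosome ", ch, " has no probes")
      next
    }
    p <- pos[sel]
    if (is.unsorted(p)) {
      o <- order(p); sel <- sel[o]; p <- p[o]
    }
    cp <- cumsum(e_pos[sel]); cn <- cumsum(e_neg[sel])
    iL <- findInterval(p - half - 0.5, p)   # probes strictly left of window
    iR <- findInterval(p + half + 0.5 - 1e-9, p)  # probes with pos <= p + half
    n_window[sel] <- iR - iL
    k_pos[sel] <- cp[iR] - c(0, cp)[iL + 1L]
    k_neg[sel] <- cn[iR] - c(0, cn)[iL + 1L]
  }
  p_tail <- function(k, nw) stats::pbinom(k - 1L, nw, 1 - q,
                                          lower.tail = FALSE)
  out <- data.frame(
    probe_id = layout$probe_id, chrom = layout$chrom, pos = pos,
    n_window = n_window, k_pos = k_pos, k_neg = k_neg,
    p_pos = p_tail(k_pos, n_window), p_neg = p_tail(k_neg, n_window),
    stringsAsFactors = FALSE
  )
  class(out) <- c("window_score", "data.frame")
  out
}

#' Merge significant windows into directional DMRs
#'
#' Probes whose window p-value in one direction is below `threshold_p`
#' (with the smaller-p direction winning if both are significant) are
#' grouped into runs separated by at most `merge_gap_bp`; runs with at
#' least `min_probes` probes become regions. Positive-t windows give
#' epithelial-methylated regions, negative-t windows fibroblast-methylated
#' ones.
#'
#' @param scores a `window_score` from [window_scan()].
#' @param layout probe layout.
#' @param threshold_p window p-value cutoff (regions require p < cutoff).
#' @param min_probes minimum supporting probes per region.
#' @param merge_gap_bp maximum gap between consecutive significant probes.
#' @return data.frame of class `dmr_regions`: `chrom`, `start`, `end`,
#'   `direction`, `n_probes`, `best_p`.
#' @export
call_regions <- function(scores, layout, threshold_p, min_probes = 4,
                         merge_gap_bp = 300) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_probes = integer(), best_p = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("dmr_regions", "data.frame")
  if (is.na(threshold_p)) return(empty)
  sig_pos <- scores$p_pos < threshold_p
  sig_neg <- scores$p_neg < threshold_p
  both <- sig_pos & sig_neg
  sig_pos[both] <- scores$p_pos[both] <= scores$p_neg[both]
  sig_neg[both] <- !sig_pos[both]
  out <- list(empty)
  for (dirn in c("pos", "neg")) {
    sig <- if (dirn == "pos") sig_pos else sig_neg
    pcol <- if (dirn == "pos") scores$p_pos else scores$p_neg
    lab <- if (dirn == "pos") "epithelial_methylated" else
      "fibroblast_methylated"
    for (ch in unique(scores$chrom)) {
      idx <- which(sig & scores$chrom == ch)
      if (!length(idx)) next
      idx <- idx[order(scores$pos[idx])]
      p <- scores$pos[idx]
      run <- cumsum(c(TRUE, diff(p) > merge_gap_bp))
      for (r in split(idx, run)) {
        if (length(r) < min_probes) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = min(layout$start[r]),
          end = max(layout$end[r]),
          direction = lab,
          n_probes = length(r),
          best_p = min(pcol[r]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), ]
  rownames(res) <- NULL
  class(res) <- c("dmr_regions", "data.frame")
  res
}

## Count called regions at each candidate cutoff without materializing
## them (hot inner loop of the calibration). Assumes `scores` rows are
## sorted by (chrom, pos), which window_scan guarantees for a sorted layout.
count_regions_at <- function(scores, layout, cutoffs, min_probes,
                             merge_gap_bp) {
  chrom_ord <- cumsum(c(0L, scores$chrom[-1] != scores$chrom[-nrow(scores)]))
  count_dir <- function(sig, pos) {
    idx <- which(sig)
    if (length(idx) < min_probes) return(0L)
    new_run <- c(TRUE, diff(pos[idx]) > merge_gap_bp |
                   diff(chrom_ord[idx]) != 0L)
    sum(tabulate(cumsum(new_run)) >= min_probes)
  }
  vapply(cutoffs, function(th) {
    sig_pos <- scores$p_pos < th
    sig_neg <- scores$p_neg < th
    both <- which(sig_pos & sig_neg)
    if (length(both)) {
      keep <- scores$p_pos[both] <= scores$p_neg[both]
      sig_pos[both] <- keep
      sig_neg[both] <- !keep
    }
    count_dir(sig_pos, scores$pos) + count_dir(sig_neg, scores$pos)
  }, integer(1))
}

#' Permutation calibration of the window p-value cutoff
#'
#' Multiple-testing control by probe-position randomization: in each
#' permutation the observed t-values are randomly reassigned to probe
#' positions (positions fixed, values shuffled) and the window scan plus
#' region merging is rerun, so any region detected on permuted data is a
#' false positive by construction. Over a descending grid of candidate
#' cutoffs, the returned threshold is the largest cutoff whose empirical
#' false-discovery estimate — mean permutation region count divided by the
#' observed region count (floored at 1) — stays below `alpha`. With
#' `mode = "fpr"` the criterion is instead that the expected number of null
#' regions per analysis is below `alpha`.
#'
#' @param tstat a `tstat_track`.
#' @param layout probe layout.
#' @param alpha false-positive control level (default 0.05).
#' @param n_perm number of permutations (default 20).
#' @param window_bp,q window-scan parameters, see [window_scan()].
#' @param min_probes,merge_gap_bp region-merging parameters, see
#'   [call_regions()].
#' @param grid descending vector of candidate p cutoffs; default a
#'   geometric grid from 0.5 down to 1e-10.
#' @param mode `"efdr"` (default) or `"fpr"`, see Details.
#' @param seed RNG seed for the permutations.
#' @return list of class `calibration_result`: `threshold_p` (NA when no
#'   cutoff attains the criterion), `n_observed`, `n_null_mean`, `efdr` at
#'   the returned cutoff, `n_permutations`, `alpha`, `mode`, and the full
#'   per-cutoff `table`.
#' @export
calibrate_threshold <- function(tstat, layout, alpha = 0.05, n_perm = 20,
                                window_bp = 300, q = 0.95, min_probes = 4,
                                merge_gap_bp = 300, grid = NULL,
                                mode = c("efdr", "fpr"), seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(grid)) grid <- 10^seq(log10(0.5), -10, length.out = 28)
  grid <- sort(grid, decreasing = TRUE)

  obs_scores <- window_scan(tstat, layout, window_bp = window_bp, q = q)
  n_obs <- count_regions_at(obs_scores, layout, grid, min_probes,
                            merge_gap_bp)

  null_counts <- matrix(0L, n_perm, length(grid))
  with_seed(seed, {
    perm <- tstat
    for (b in seq_len(n_perm)) {
      perm$t <- sample(tstat$t)
      sc <- window_scan(perm, layout, window_bp = window_bp, q = q)
      null_counts[b, ] <- count_regions_at(sc, layout, grid, min_probes,
                                           merge_gap_bp)
    }
  })
  n_null_mean <- colMeans(null_counts)
  efdr <- n_null_mean / pmax(n_obs, 1)
  crit <- if (mode == "efdr") efdr < alpha else n_null_mean < alpha
  if (alpha >= 1) crit[] <- TRUE   # vacuous constraint: loosest cutoff wins
  pick <- which(crit)[1]   # grid is descending: first hit = largest cutoff

  res <- list(
    threshold_p = if (length(pick) && !is.na(pick)) grid[pick] else NA_real_,
    n_observed = if (!is.na(pick)) n_obs[pick] else 0L,
    n_null_mean = if (!is.na(pick)) n_null_mean[pick] else NA_real_,
    efdr = if (!is.na(pick)) efdr[pick] else NA_real_,
    n_permutations = n_perm,
    alpha = alpha,
    mode = mode,
    table = data.frame(cutoff = grid, n_observed = n_obs,
                       n_null_mean = n_null_mean, efdr = efdr)
  )
  class(res) <- "calibration_result"
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  if (is.na(x$threshold_p)) {
    cat("calibration: no cutoff attains", x$mode, "<", x$alpha,
        "- reporting 0 regions\n")
  } else {
    cat(sprintf(
      "calibration: cutoff %.3g -> %d regions (null mean %.2f, eFDR %.3f) at %s < %.3g over %d permutations\n",
      x$threshold_p, x$n_observed, x$n_null_mean, x$efdr, x$mode, x$alpha,
      x$n_permutations))
  }
  invisible(x)
}

#' One-call DMR detection
#'
#' Runs [paired_t()], [calibrate_threshold()] and [call_regions()] on a
#' normalized signal matrix.
#'
#' @inheritParams calibrate_threshold
#' @param m a normalized `signal_matrix`.
#' @param sheet paired sample sheet.
#' @return list with `regions` (a `dmr_regions`), `calibration` and `tstat`.
#' @export
detect_dmrs <- function(m, layout, sheet = m$sheet, alpha = 0.05,
                        n_perm = 20, window_bp = 300, q = 0.95,
                        min_probes = 4, merge_gap_bp = 300, seed = NULL,
                        mode = "efdr") {
  tstat <- paired_t(m, sheet)
  cal <- calibrate_threshold(tstat, layout, alpha = alpha, n_perm = n_perm,
                             window_bp = window_bp, q = q,
                             min_probes = min_probes,
                             merge_gap_bp = merge_gap_bp, seed = seed,
                             mode = mode)
  scores <- window_scan(tstat, layout, window_bp = window_bp, q = q)
  regions <- call_regions(scores, layout, cal$threshold_p,
                          min_probes = min_probes,
                          merge_gap_bp = merge_gap_bp)
  list(regions = regions, calibration = cal, tstat = tstat,
       scores = scores)
}
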