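# Hand-built fixtures and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the package internals.

## A minimal probe_layout from explicit probe start positions.
tiny_layout <- function(pos, chrom = "chr1", len = 25L) {
  df <- data.frame(
    probe_id = sprintf("p%04d", seq_along(pos)),
    chrom = rep_len(chrom, length(pos)),
    start = as.integer(pos),
    end = as.integer(pos) + len,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  nc <- ceiling(sqrt(nrow(df)))
  idx <- seq_len(nrow(df)) - 1L
  df$array_row <- idx %/% nc + 1L
  df$array_col <- idx %% nc + 1L
  class(df) <- c("probe_layout", "data.frame")
  df
}

## A paired sheet for n genotypes.
tiny_sheet <- function(n = 3) {
  data.frame(
    sample_id = paste0("g", rep(seq_len(n), each = 2), "_",
                       rep(c("e", "f"), n)),
    genotype = paste0("g", rep(seq_len(n), each = 2)),
    cell_type = rep(c("epithelial", "fibroblast"), n),
    stringsAsFactors = FALSE
  )
}

## signal_matrix whose paired differences are exactly `d` (per genotype)
## for every probe; epithelial = base + d_g, fibroblast = base.
diff_signal <- function(d, layout, base = 8, stage = "quantile") {
  sheet <- tiny_sheet(length(d))
  vals <- matrix(base, nrow(layout), nrow(sheet),
                 dimnames = list(layout$probe_id, sheet$sample_id))
  for (g in seq_along(d))
    vals[, sheet$genotype == paste0("g", g) &
           sheet$cell_type == "epithelial"] <- base + d[g]
  m <- signal_matrix(vals, layout, sheet, stage = "raw")
  m$stage <- stage
  m
}

## All-pairs nearest TSS: signed distance, ties to first in sorted order.
bf_nearest_tss <- function(regions, tss) {
  tss <- tss[order(tss$chrom, tss$pos), ]
  mid <- floor((regions$start + regions$end) / 2)
  t(vapply(seq_len(nrow(regions)), function(i) {
    cand <- which(tss$chrom == regions$chrom[i])
    du <- abs(mid[i] - tss$pos[cand])
    k <- cand[which.min(du)]   # which.min = first minimum in sorted order
    d <- mid[i] - tss$pos[k]
    if (tss$strand[k] == "-") d <- -d
    c(idx = k, dist = d)
  }, c(idx = 0, dist = 0)))
}

## All-pairs nearest island gap distance.
bf_nearest_island <- function(regions, islands) {
  islands <- islands[order(islands$chrom, islands$start, islands$end), ]
  vapply(seq_len(nrow(regions)), function(i) {
    cand <- which(islands$chrom == regions$chrom[i])
    gaps <- pmax(islands$start[cand] - regions$end[i],
                 regions$start[i] - islands$end[cand], 0)
    min(gaps)
  }, numeric(1))
}

## Quadratic-time overlap partition of two region sets.
bf_venn <- function(a, b) {
  ov <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i)
      any(y$chrom == x$chrom[i] & y$start < x$end[i] & y$end > x$start[i]),
      logical(1))
  }
  sa <- sum(ov(a, b)); sb <- sum(ov(b, a))
  c(only_A = nrow(a) - sa, only_B = nrow(b) - sb,
    shared_A = sa, shared_B = sb)
}

## Independent exact two-sided rank-sum p: enumerate group assignments and
## score with the Mann-Whitney U statistic (pairwise comparisons, ties 0.5).
bf_rank_sum_p <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  pooled <- c(x, y)
  nA <- length(x)
  mu <- nA * length(y) / 2
  obs <- abs(u_stat(x, y) - mu)
  cmb <- utils::combn(length(pooled), nA)
  stats <- apply(cmb, 2, function(ix)
    abs(u_stat(pooled[ix], pooled[-ix]) - mu))
  mean(stats >= obs - 1e-9)
}

## Random region set on a single synthetic chromosome.
random_regions <- function(n, max_pos = 100000, min_len = 50, max_len = 2000) {
  s <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  data.frame(chrom = "chr1", start = s, end = s + len,
             stringsAsFactors = FALSE)
}
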