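#' Venn partition of two DMR sets
#'
#' A region is "shared" if it overlaps at least 1 bp of any region of the
#' other set; shared counts are evaluated per set, so they may differ when
#' the two sets have different granularity. When a probe layout is given,
#' the probes covered by each partition class are also counted (a probe
#' overlapping regions of both sets counts as shared).
#'
#' @param setA,setB region data.frames (`chrom`, `start`, `end`).
#' @param layout optional probe layout for probe counts.
#' @return list of class `overlap_result` with `n_only_A`, `n_only_B`,
#'   `n_shared_A`, `n_shared_B` and, when a layout is given, probe counts
#'   `probes_only_A`, `probes_only_B`, `probes_shared`.
#' @export
venn <- function(setA, setB, layout = NULL) {
  stop_if_mixed_chroms(setA, setB)
  ga <- as_granges0(setA[c("chrom", "start", "end")])
  gb <- as_granges0(setB[c("chrom", "start", "end")])
  sharedA <- sum(GenomicRanges::countOverlaps(ga, gb) > 0)
  sharedB <- sum(GenomicRanges::countOverlaps(gb, ga) > 0)
  res <- list(
    n_only_A = nrow(setA) - sharedA,
    n_only_B = nrow(setB) - sharedB,
    n_shared_A = sharedA,
    n_shared_B = sharedB
  )
  if (!is.null(layout)) {
    gp <- as_granges0(layout[c("chrom", "start", "end")])
    inA <- GenomicRanges::countOverlaps(gp, ga) > 0
    inB <- GenomicRanges::countOverlaps(gp, gb) > 0
    res$probes_only_A <- sum(inA & !inB)
    res$probes_only_B <- sum(inB & !inA)
    res$probes_shared <- sum(inA & inB)
  }
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap: only A =", x$n_only_A, "| shared (A persp.) =", x$n_shared_A,
      "| shared (B persp.) =", x$n_shared_B, "| only B =", x$n_only_B, "\n")
  if (!is.null(x$p_emp))
    cat(sprintf("permutation test: observed %d shared, null mean %.1f, p = %.4g (%d iterations)\n",
                x$n_shared_A, mean(x$null_overlaps), x$p_emp,
                x$n_iterations))
  invisible(x)
}

#' Coverage-respecting overlap permutation test
#'
#' Tests whether the number of set-A regions overlapping set B exceeds
#' chance: each iteration re-places set A's regions (lengths preserved)
#' with starts drawn uniformly over probe-covered bases, holding set B
#' fixed, and records the shared count. The empirical p-value uses the
#' add-one correction (1 + #\{null >= observed\}) / (n_iter + 1), so it is
#' never exactly zero.
#'
#' @param setA,setB region data.frames (`chrom`, `start`, `end`).
#' @param layout probe layout defining coverage.
#' @param n_iter number of placement iterations (default 5000).
#' @param seed RNG seed.
#' @return an `overlap_result` with additional fields `null_overlaps`,
#'   `n_iterations`, `p_emp`.
#' @export
overlap_permutation <- function(setA, setB, layout, n_iter = 5000,
                                seed = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  res <- venn(setA, setB, layout = layout)
  segs <- coverage_segments(layout)
  lengths <- setA$end - setA$start
  ## merged set-B intervals per chromosome for a fast findInterval-based
  ## overlap count in the permutation loop
  gb <- GenomicRanges::reduce(as_granges0(setB[c("chrom", "start", "end")]))
  red <- split(
    data.frame(start = GenomicRanges::start(gb) - 1L,
               end = GenomicRanges::end(gb)),
    as.character(GenomicRanges::seqnames(gb))
  )
  count_shared <- function(rnd) {
    tot <- 0L
    for (ch in unique(rnd$chrom)) {
      rb <- red[[ch]]
      if (is.null(rb)) next
      sel <- rnd$chrom == ch
      s <- rnd$start[sel]; e <- rnd$end[sel]
      i <- findInterval(s, rb$start)
      hit_left <- i >= 1L & rb$end[pmax(i, 1L)] > s
      j <- pmin(i + 1L, nrow(rb))
      hit_right <- i < nrow(rb) & rb$start[j] < e
      tot <- tot + sum(hit_left | hit_right)
    }
    tot
  }
  null <- integer(n_iter)
  with_seed(seed, {
    for (b in seq_len(n_iter)) {
      rnd <- sample_covered_regions(segs, lengths)
      null[b] <- count_shared(rnd)
    }
  })
  res$null_overlaps <- null
  res$n_iterations <- n_iter
  res$p_emp <- (1 + sum(null >= res$n_shared_A)) / (n_iter + 1)
  res
}

#' Relative excess of one DMR total over another
#'
#' 100 * (total_B - total_A) / total_A, with the rounded value (nearest
#' integer, ties away from zero) reported alongside.
#'
#' @param countsA,countsB numeric vectors of category counts (summed to
#'   totals).
#' @return list with `percent` (exact) and `rounded`.
#' @export
relative_excess <- function(countsA, countsB) {
  ta <- sum(countsA); tb <- sum(countsB)
  if (ta <= 0) stop("total of countsA must be positive")
  pct <- 100 * (tb - ta) / ta
  list(percent = pct, rounded = sign(pct) * floor(abs(pct) + 0.5),
       rounding = "nearest integer, ties away from zero")
}
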