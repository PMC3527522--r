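#' Nearest transcription start site for each region
#'
#' Distance is measured from the region midpoint to the TSS position and
#' signed by transcript orientation: negative means upstream of the TSS
#' (genome-left of a plus-strand TSS, genome-right of a minus-strand one).
#' Among TSS at equal unsigned distance the first in (chrom, pos) sorted
#' order is reported.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `region_id`.
#' @param tss feature table with `chrom`, `pos`, `strand`, `name`.
#' @return data.frame `region_id`, `nearest_tss_name`, `tss_distance`.
#' @export
nearest_tss <- function(regions, tss) {
  if (!nrow(tss)) stop("empty TSS table")
  stopifnot(all(c("chrom", "pos", "strand", "name") %in% names(tss)),
            all(tss$strand %in% c("+", "-")))
  stop_if_mixed_chroms(regions, data.frame(chrom = tss$chrom),
                       c("regions", "TSS table"))
  tss <- tss[order(tss$chrom, tss$pos), ]
  mid <- region_midpoint(regions)
  n <- nrow(regions)
  pick <- integer(n)
  for (ch in unique(regions$chrom)) {
    rsel <- which(regions$chrom == ch)
    tsel <- which(tss$chrom == ch)
    if (!length(tsel))
      stop("no TSS on chromosome ", ch)
    p <- tss$pos[tsel]
    i <- findInterval(mid[rsel], p)
    left <- pmax(i, 1L)
    right <- pmin(i + 1L, length(p))
    dl <- abs(mid[rsel] - p[left])
    dr <- abs(mid[rsel] - p[right])
    ## ties go to the left neighbour = first in sorted order
    use_left <- (i >= 1L) & (i >= length(p) | dl <= dr)
    pick[rsel] <- tsel[ifelse(use_left, left, right)]
  }
  d_unsigned <- mid - tss$pos[pick]
  d <- ifelse(tss$strand[pick] == "+", d_unsigned, -d_unsigned)
  data.frame(
    region_id = regions$region_id %||%
      sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end),
    nearest_tss_name = tss$name[pick],
    tss_distance = as.integer(d),
    stringsAsFactors = FALSE
  )
}

#' Nearest CpG island for each region
#'
#' Reports the gap in bp between the closest edges of the region and its
#' nearest island; 0 when they overlap or are bookended. Ties are broken
#' by first island in (chrom, start) sorted order.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param islands feature table with `chrom`, `start`, `end`, `name`.
#' @return data.frame `region_id`, `nearest_island_name`, `island_distance`.
#' @export
nearest_island <- function(regions, islands) {
  if (!nrow(islands)) stop("empty island table")
  stop_if_mixed_chroms(regions, islands, c("regions", "island table"))
  islands <- islands[order(islands$chrom, islands$start, islands$end), ]
  rgr <- as_granges0(regions[c("chrom", "start", "end")])
  igr <- as_granges0(islands[c("chrom", "start", "end")])
  hits <- GenomicRanges::distanceToNearest(rgr, igr, select = "all")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ## among ties keep the smallest subject index = first in sorted order
  o <- order(qh, sh)
  qh <- qh[o]; sh <- sh[o]
  dd <- S4Vectors::mcols(hits)$distance[o]
  first <- !duplicated(qh)
  pick <- rep(NA_integer_, nrow(regions))
  dist <- rep(NA_integer_, nrow(regions))
  pick[qh[first]] <- sh[first]
  dist[qh[first]] <- dd[first]
  if (anyNA(pick))
    stop("no island on the chromosome of ",
         sum(is.na(pick)), " region(s)")
  data.frame(
    region_id = regions$region_id %||%
      sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end),
    nearest_island_name = islands$name[pick],
    island_distance = as.integer(dist),
    stringsAsFactors = FALSE
  )
}

## Distances from randomly placed or observed regions to features,
## used by positional_null(); `type` picks the distance definition.
feature_distances <- function(regions, features, type = c("tss", "island")) {
  type <- match.arg(type)
  if (type == "tss") nearest_tss(regions, features)$tss_distance
  else nearest_island(regions, features)$island_distance
}

#' Coverage-corrected positional null for region-to-feature distances
#'
#' Builds the expected distance distribution if regions were placed at
#' random while respecting the uneven probe coverage of the array: each
#' iteration re-places the observed regions (lengths preserved) with start
#' positions drawn uniformly over probe-covered bases, recomputes
#' nearest-feature distances and bins them on the same edges as the
#' observed distances. Per-bin means and a central `ci` band (percentiles
#' over iterations) summarize the null.
#'
#' @param regions observed regions (`chrom`, `start`, `end`).
#' @param layout probe layout defining coverage.
#' @param features TSS table (with `pos`, `strand`) or island table (with
#'   `start`, `end`); picked by `type`.
#' @param type `"tss"` (signed distances) or `"island"` (gap distances).
#' @param bin_edges histogram bin edges; default +/- 8 kb at 250 bp for TSS,
#'   0..8 kb for islands.
#' @param n_iter number of placement iterations (default 1000).
#' @param ci central band mass (default 0.99).
#' @param seed RNG seed.
#' @return list of class `positional_null`: `bin_edges`, `observed`,
#'   `null_mean`, `lower`, `upper`, `n_iterations`.
#' @export
positional_null <- function(regions, layout, features,
                            type = c("tss", "island"), bin_edges = NULL,
                            n_iter = 1000, ci = 0.99, seed = NULL) {
  type <- match.arg(type)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(bin_edges))
    bin_edges <- if (type == "tss") seq(-8000, 8000, by = 250) else
      seq(0, 8000, by = 250)
  nb <- length(bin_edges) - 1L
  bin_counts <- function(d) {
    b <- findInterval(d, bin_edges, rightmost.closed = TRUE)
    tabulate(b[b >= 1L & b <= nb], nbins = nb)
  }
  observed <- bin_counts(feature_distances(regions, features, type))
  segs <- coverage_segments(layout)
  lengths <- regions$end - regions$start
  null <- matrix(0L, n_iter, nb)
  with_seed(seed, {
    for (b in seq_len(n_iter)) {
      rnd <- sample_covered_regions(segs, lengths)
      null[b, ] <- bin_counts(feature_distances(rnd, features, type))
    }
  })
  a <- (1 - ci) / 2
  res <- list(
    bin_edges = bin_edges,
    observed = observed,
    null_mean = colMeans(null),
    lower = apply(null, 2, stats::quantile, probs = a, names = FALSE),
    upper = apply(null, 2, stats::quantile, probs = 1 - a, names = FALSE),
    n_iterations = n_iter,
    ci = ci
  )
  class(res) <- "positional_null"
  res
}

#' @export
print.positional_null <- function(x, ...) {
  out_of_band <- sum(x$observed < x$lower | x$observed > x$upper)
  cat("positional_null:", length(x$observed), "bins,", x$n_iterations,
      "iterations;", out_of_band, "bin(s) outside the",
      paste0(100 * x$ci, "%"), "band\n")
  invisible(x)
}

#' Genes with a region within a TSS-distance cutoff
#'
#' Selects the unique nearest-gene names of all regions whose unsigned TSS
#' distance is at most `cutoff` ("within 2 kbp" read inclusively), the
#' gene-list input for downstream enrichment analysis.
#'
#' @param records output of [nearest_tss()].
#' @param cutoff distance cutoff in bp (default 2000).
#' @return character vector of unique gene names.
#' @export
genes_within_2kb <- function(records, cutoff = 2000) {
  unique(records$nearest_tss_name[abs(records$tss_distance) <= cutoff])
}
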