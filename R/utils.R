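## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a region or probe table to a GRanges
#'
#' Coordinates throughout the package are 0-based half-open (BED
#' convention); GRanges is 1-based closed, so starts are shifted by one.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @return A [GenomicRanges::GRanges] object carrying the remaining columns
#'   as metadata.
#' @keywords internal
as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[extra]
  gr
}

## Probe-covered bases of the array as a set of disjoint segments
## (data.frame chrom/start/end, 0-based half-open), obtained by merging
## overlapping and bookended probe intervals.
coverage_segments <- function(layout) {
  gr <- GenomicRanges::reduce(as_granges0(layout))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

## Sample `n` region start positions uniformly over probe-covered bases.
## `segs` comes from coverage_segments(); lengths are attached so the
## sampled regions reproduce the observed length distribution. Relies on
## the caller having set the RNG state.
sample_covered_regions <- function(segs, lengths) {
  n <- length(lengths)
  w <- segs$end - segs$start
  cw <- cumsum(w)
  total <- cw[length(cw)]
  u <- sample.int(total, n, replace = TRUE)          # 1..total
  seg <- findInterval(u - 1L, c(0L, cw[-length(cw)]))
  off <- u - 1L - c(0L, cw[-length(cw)])[seg]        # 0-based offset in segment
  start <- segs$start[seg] + off
  data.frame(
    chrom = segs$chrom[seg],
    start = start,
    end   = start + lengths,
    stringsAsFactors = FALSE
  )
}

## Scoped seeding: set the seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Region midpoints (0-based coordinate of the central base).
region_midpoint <- function(df) as.integer(floor((df$start + df$end) / 2))

stop_if_mixed_chroms <- function(a, b, what = c("set A", "set B")) {
  ca <- unique(as.character(a$chrom)); cb <- unique(as.character(b$chrom))
  if (length(ca) && length(cb) && !length(intersect(ca, cb))) {
    stop("no shared chromosome names between ", what[1], " (", ca[1], ", ...) and ",
         what[2], " (", cb[1], ", ...); check chromosome naming conventions",
         call. = FALSE)
  }
  invisible(TRUE)
}
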