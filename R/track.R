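#' Fixed-step genomic signal track
#'
#' A per-chromosome vector of signal values at fixed bin width, the
#' container used for histone-enrichment profiles. Bin i covers bases
#' `[(i-1)*step, i*step)` (0-based). Queries outside coverage return `NA`.
#'
#' @param values named list, one numeric vector per chromosome.
#' @param step bin width in bp.
#' @return object of class `genomic_track`.
#' @export
genomic_track <- function(values, step = 50L) {
  stopifnot(is.list(values), !is.null(names(values)), step > 0,
            all(vapply(values, is.numeric, logical(1))))
  structure(list(values = values, step = as.integer(step)),
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  cat("genomic_track: step", x$step, "bp;",
      paste(names(x$values), vapply(x$values, length, 1L),
            "bins", collapse = ", "), "\n")
  invisible(x)
}

#' Look up track values at genomic positions
#'
#' @param track a [genomic_track()].
#' @param chrom chromosome name (scalar or vector recycled against `pos`).
#' @param pos 0-based base positions.
#' @return numeric vector; `NA` outside track coverage.
#' @export
track_value <- function(track, chrom, pos) {
  stopifnot(inherits(track, "genomic_track"))
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    v <- track$values[[ch]]
    sel <- chrom == ch
    if (is.null(v)) next
    bin <- pos[sel] %/% track$step + 1L
    ok <- pos[sel] >= 0 & bin <= length(v)
    res <- rep(NA_real_, sum(sel))
    res[ok] <- v[bin[ok]]
    out[sel] <- res
  }
  out
}

#' Read a bedGraph file into a fixed-step track
#'
#' Intervals are resampled onto a regular `step`-bp grid by
#' coverage-weighted mean; grid bins not touched by any interval are `NA`.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param step target bin width in bp.
#' @return a [genomic_track()].
#' @export
read_bedgraph <- function(path, step = 50L) {
  bg <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  step <- as.integer(step)
  vals <- lapply(split(bg, bg$chrom), function(d) {
    nbin <- as.integer(ceiling(max(d$end) / step))
    num <- numeric(nbin); den <- numeric(nbin)
    for (i in seq_len(nrow(d))) {
      b0 <- d$start[i] %/% step + 1L
      b1 <- (d$end[i] - 1L) %/% step + 1L
      for (b in b0:b1) {
        lo <- max(d$start[i], (b - 1L) * step)
        hi <- min(d$end[i], b * step)
        num[b] <- num[b] + d$value[i] * (hi - lo)
        den[b] <- den[b] + (hi - lo)
      }
    }
    out <- num / den
    out[den == 0] <- NA_real_
    out
  })
  genomic_track(vals, step = step)
}

#' Write a fixed-step track as bedGraph
#'
#' @param track a [genomic_track()].
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    keep <- !is.na(v)
    idx <- which(keep)
    if (!length(idx)) next
    df <- data.frame(chrom = ch, start = (idx - 1L) * track$step,
                     end = idx * track$step, value = v[idx])
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
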