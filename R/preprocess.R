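#' Log2-transform raw probe intensities
#'
#' @param m a `signal_matrix` at stage `"raw"` with strictly positive values.
#' @return a `signal_matrix` at stage `"logged"`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  if (m$stage != "raw")
    stop("log2_transform expects stage 'raw', got '", m$stage, "'")
  bad <- which(!(m$values > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity at probe '", m$probe_ids[bad[1, 1]],
         "', sample '", colnames(m$values)[bad[1, 2]], "' (",
         nrow(bad), " offending value(s) in total)", call. = FALSE)
  }
  m$values <- log2(m$values)
  m$stage <- "logged"
  m
}

#' Per-array spatial normalization
#'
#' Removes smooth local hybridization bias on each array: the probe values
#' are arranged on the physical (row, col) grid, a running 2-D median
#' surface (window `k` x `k`, edge-truncated) is subtracted, and the
#' array's global median is added back so the array-level location is
#' preserved. Robust to DMR-induced outliers because the surface is a
#' median, not a mean.
#'
#' @param m a `signal_matrix` at stage `"logged"`.
#' @param layout the probe layout supplying grid coordinates.
#' @param k median-filter window size (odd; default 15).
#' @return a `signal_matrix` at stage `"spatial"`.
#' @export
spatial_normalize <- function(m, layout, k = 15L) {
  stopifnot(inherits(m, "signal_matrix"), inherits(layout, "probe_layout"))
  if (m$stage != "logged")
    stop("spatial_normalize expects stage 'logged', got '", m$stage, "'")
  k <- as.integer(k)
  nr <- max(layout$array_row); nc <- max(layout$array_col)
  if (nr * nc < k * k) {
    warning("array grid (", nr, "x", nc, ") smaller than filter window; ",
            "falling back to global-median-only correction")
    m$stage <- "spatial"
    return(m)
  }
  idx <- cbind(layout$array_row, layout$array_col)
  for (j in seq_len(ncol(m$values))) {
    grid <- matrix(NA_real_, nr, nc)
    grid[idx] <- m$values[, j]
    surf <- .median_filter_2d(grid, k)
    med <- stats::median(m$values[, j])
    v <- m$values[, j] - surf[idx]
    # re-center so the array's global median is preserved exactly
    m$values[, j] <- v - stats::median(v) + med
  }
  m$stage <- "spatial"
  m
}

#' Cross-array quantile normalization
#'
#' Forces all samples onto a common intensity distribution: each sample's
#' sorted values are replaced by the across-sample mean of sorted values.
#' Tied values within a sample receive the mean of the reference values
#' over their tied ranks, so the sorted value vectors of all samples are
#' exactly equal afterwards and within-sample rank order is preserved.
#'
#' @param m a `signal_matrix` at stage `"spatial"` (or `"logged"`).
#' @return a `signal_matrix` at stage `"quantile"`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  if (!m$stage %in% c("logged", "spatial"))
    stop("quantile_normalize expects stage 'logged' or 'spatial', got '",
         m$stage, "'")
  x <- m$values
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 samples")
  if (anyNA(x)) stop("quantile normalization does not accept missing values")
  ref <- rowMeans(apply(x, 2, sort, method = "radix"))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j], method = "radix")
    ## average the reference over runs of tied input values
    xo <- x[o, j]
    r <- rle(xo)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cs <- cumsum(ref)
    gm <- (cs[ends] - c(0, cs)[starts]) / r$lengths
    out[o, j] <- rep(gm, r$lengths)
  }
  m$values <- out
  m$stage <- "quantile"
  m
}

#' Run the full normalization chain
#'
#' Convenience wrapper: log2 transform, spatial normalization, quantile
#' normalization, in that order.
#'
#' @inheritParams spatial_normalize
#' @param m a `signal_matrix` at stage `"raw"`.
#' @return a `signal_matrix` at stage `"quantile"`.
#' @export
preprocess <- function(m, layout, k = 15L) {
  quantile_normalize(spatial_normalize(log2_transform(m), layout, k = k))
}
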