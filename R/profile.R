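#' Extract signal-track profiles around regions
#'
#' Samples the track at every signed offset from each region midpoint over
#' `-flank..+flank` bp at the track's bin resolution. Tracks are
#' unstranded, so no orientation flipping is applied. Offsets that fall
#' outside track coverage give `NA`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `direction` (used as the class label; defaults to `"all"`).
#' @param track a [genomic_track()].
#' @param flank half-width of the window in bp (default 10000); must be a
#'   multiple of the track step.
#' @return list of class `profile_matrix`: `values` (regions x offsets),
#'   `offsets`, `class` (per-region labels).
#' @export
extract_profiles <- function(regions, track, flank = 10000) {
  stopifnot(inherits(track, "genomic_track"))
  if (flank %% track$step != 0)
    stop("track resolution (", track$step, " bp) must divide flank (",
         flank, " bp)")
  offsets <- seq(-flank, flank, by = track$step)
  mid <- region_midpoint(regions)
  vals <- matrix(NA_real_, nrow(regions), length(offsets))
  for (j in seq_along(offsets))
    vals[, j] <- track_value(track, regions$chrom, mid + offsets[j])
  structure(list(
    values = vals,
    offsets = offsets,
    class = regions$direction %||% rep("all", nrow(regions))
  ), class = "profile_matrix")
}

## Centred moving average, missing-aware, edge windows truncated.
moving_average <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
}

#' Aggregate profiles into per-class moving-average curves
#'
#' For each region class, the column-wise mean over regions is taken
#' (ignoring missing values) and smoothed with a centred moving average of
#' `window_bins` bins (truncated at the edges).
#'
#' @param pm a `profile_matrix` from [extract_profiles()].
#' @param window_bins moving-average width in bins (default 11).
#' @return list of class `profile_curves`: `offsets` and `curves`, a named
#'   list with one numeric curve per class.
#' @export
aggregate_moving_average <- function(pm, window_bins = 11) {
  stopifnot(inherits(pm, "profile_matrix"))
  classes <- unique(pm$class)
  curves <- list()
  for (cl in classes) {
    rows <- pm$values[pm$class == cl, , drop = FALSE]
    keep <- rowSums(!is.na(rows)) > 0
    if (!any(keep)) {
      warning("class '", cl, "' has no regions with data; omitted")
      next
    }
    colmean <- colMeans(rows[keep, , drop = FALSE], na.rm = TRUE)
    colmean[is.nan(colmean)] <- NA_real_
    curves[[cl]] <- moving_average(colmean, window_bins)
  }
  structure(list(offsets = pm$offsets, curves = curves),
            class = "profile_curves")
}

#' Random-region control curve
#'
#' Places `n` regions with the given lengths uniformly over probe-covered
#' bases and applies the same extraction and aggregation, yielding the
#' coverage-matched control curve against which class curves are judged.
#'
#' @param layout probe layout defining coverage.
#' @param n number of control regions.
#' @param lengths region lengths (recycled to `n`).
#' @param track a [genomic_track()].
#' @param flank half-width in bp.
#' @param window_bins moving-average width in bins.
#' @param seed RNG seed.
#' @return a `profile_curves` object with one curve named `"control"`.
#' @export
random_region_control <- function(layout, n, lengths, track, flank = 10000,
                                  window_bins = 11, seed = NULL) {
  segs <- coverage_segments(layout)
  rnd <- with_seed(seed,
                   sample_covered_regions(segs, rep_len(lengths, n)))
  rnd$direction <- "control"
  aggregate_moving_average(extract_profiles(rnd, track, flank = flank),
                           window_bins = window_bins)
}
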