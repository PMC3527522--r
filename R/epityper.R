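#' Load a CpG-unit methylation matrix from long-format TSV
#'
#' Expected columns: `region_id`, `unit_id`, `sample_id`, `fraction`, and
#' optionally `cell_type`. Rows with fractions outside [0, 1] are dropped
#' (quality control) and counted; explicit `NA` fractions are kept as
#' missing entries. Duplicate (region, unit, sample) keys are an error.
#'
#' @param path TSV file path.
#' @return a `cpg_unit_matrix` data.frame; the number of QC-dropped rows is
#'   attached as attribute `"n_dropped"`.
#' @export
load_cpg_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("region_id", "unit_id", "sample_id", "fraction")
  if (!all(need %in% names(df))) {
    stop("malformed CpG-unit file: needs columns ",
         paste(need, collapse = ", "))
  }
  if (!is.numeric(df$fraction)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$fraction))) &
                   !is.na(df$fraction) & df$fraction != "NA")
    stop("malformed fraction values at data line(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  key <- paste(df$region_id, df$unit_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (region, unit, sample) entries, e.g. data line ",
         which(duplicated(key))[1])
  }
  bad <- !is.na(df$fraction) & (df$fraction < 0 | df$fraction > 1)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad)
  class(out) <- c("cpg_unit_matrix", "data.frame")
  out
}

## Exact two-sided rank-sum p-value by enumeration of all assignments of
## the pooled (mid)ranks to group A; used for small groups where the exact
## null distribution under ties matters.
rank_sum_exact <- function(x, y) {
  r <- rank(c(x, y))
  nA <- length(x); N <- length(r)
  w <- sum(r[seq_len(nA)])
  mu <- nA * (N + 1) / 2
  cmb <- combn(N, nA)
  ws <- colSums(matrix(r[cmb], nrow = nA))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

## Normal approximation with tie correction (no continuity correction).
rank_sum_normal <- function(x, y) {
  r <- rank(c(x, y))
  nA <- length(x); nB <- length(y); N <- nA + nB
  w <- sum(r[seq_len(nA)])
  mu <- nA * (N + 1) / 2
  ties <- table(r)
  sig2 <- nA * nB / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  min(1, 2 * stats::pnorm(-abs(w - mu) / sqrt(sig2)))
}

#' Per-region group comparison of CpG-unit methylation
#'
#' For each region, all observed unit-by-sample methylation fractions of
#' the two classes are pooled and compared with a two-sided Wilcoxon
#' rank-sum test: exact by enumeration when both classes have at most
#' `exact_max` values, normal approximation with tie correction otherwise.
#' The mean difference is mean(class A) - mean(class B) over observed
#' values. Regions with fewer than `min_values` observed values in either
#' class are flagged insufficient and get no p-value.
#'
#' @param m a `cpg_unit_matrix` (needs a `cell_type` or `class` column, or
#'   pass a `sheet` mapping `sample_id` to `cell_type`).
#' @param classA,classB class labels to compare (e.g. `"epithelial"`,
#'   `"fibroblast"`).
#' @param sheet optional sample sheet supplying `cell_type` per sample.
#' @param min_values minimum observed values per class (default 3).
#' @param exact_max largest per-class size for the exact test (default 10).
#' @return data.frame of class `region_test_result`: `region_id`,
#'   `mean_diff`, `p`, `n_A`, `n_B`, `sufficient`.
#' @export
region_tests <- function(m, classA = "epithelial", classB = "fibroblast",
                         sheet = NULL, min_values = 3, exact_max = 10) {
  df <- as.data.frame(m)
  if (is.null(df$cell_type) && !is.null(df$class)) df$cell_type <- df$class
  if (is.null(df$cell_type)) {
    if (is.null(sheet))
      stop("no cell_type column and no sample sheet supplied")
    df$cell_type <- sheet$cell_type[match(df$sample_id, sheet$sample_id)]
  }
  if (!any(df$cell_type == classA) || !any(df$cell_type == classB))
    stop("both classes must be present in the data")
  out <- lapply(split(df, df$region_id), function(d) {
    a <- d$fraction[d$cell_type == classA & !is.na(d$fraction)]
    b <- d$fraction[d$cell_type == classB & !is.na(d$fraction)]
    suff <- length(a) >= min_values && length(b) >= min_values
    p <- NA_real_
    if (suff) {
      p <- if (length(a) <= exact_max && length(b) <= exact_max)
        rank_sum_exact(a, b) else rank_sum_normal(a, b)
    }
    data.frame(
      region_id = d$region_id[1],
      mean_diff = if (length(a) && length(b)) mean(a) - mean(b) else NA_real_,
      p = p, n_A = length(a), n_B = length(b), sufficient = suff,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("region_test_result", "data.frame")
  res
}

#' Hierarchical-clustering orderings for a CpG-unit heatmap
#'
#' Casts the long matrix to (region, unit) rows by sample columns, removes
#' all-missing rows and columns, and orders each axis by agglomerative
#' clustering (average linkage on Euclidean distances computed over
#' pairwise-complete entries). Rows and columns are put into a canonical
#' lexicographic order before clustering, so the result is deterministic
#' and invariant to the input row order.
#'
#' @param m a `cpg_unit_matrix`.
#' @return list with `row_order` and `col_order` (character vectors of
#'   row keys `region|unit` and sample ids in heatmap order), `matrix`
#'   (the wide matrix in input canonical order), and `excluded` (all-missing
#'   rows/columns that were dropped).
#' @export
cluster_order <- function(m) {
  df <- as.data.frame(m)
  df$row_key <- paste(df$region_id, df$unit_id, sep = "|")
  rows <- sort(unique(df$row_key))
  cols <- sort(unique(df$sample_id))
  wide <- matrix(NA_real_, length(rows), length(cols),
                 dimnames = list(rows, cols))
  wide[cbind(match(df$row_key, rows), match(df$sample_id, cols))] <-
    df$fraction
  drop_r <- rowSums(!is.na(wide)) == 0
  drop_c <- colSums(!is.na(wide)) == 0
  excluded <- list(rows = rows[drop_r], cols = cols[drop_c])
  wide <- wide[!drop_r, !drop_c, drop = FALSE]
  if (nrow(wide) < 2 || ncol(wide) < 2)
    stop("need at least 2 non-missing rows and columns to cluster")
  hr <- stats::hclust(stats::dist(wide), method = "average")
  hc <- stats::hclust(stats::dist(t(wide)), method = "average")
  list(
    row_order = rownames(wide)[hr$order],
    col_order = colnames(wide)[hc$order],
    matrix = wide,
    excluded = excluded
  )
}
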