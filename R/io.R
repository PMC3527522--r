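## Plain-text readers/writers for the package's tabular interchange formats.
## All genomic coordinates on disk are BED-style 0-based half-open.

#' Write / read a probe layout (BED6 + grid columns)
#'
#' Columns: chrom, start, end, probe_id, score (0), strand (.), array_row,
#' array_col. The promoter/TSS table, when present, is written alongside as
#' `<path>.tss.tsv` and restored on read.
#'
#' @param layout a `probe_layout`.
#' @param path output file.
#' @export
write_layout <- function(layout, path) {
  df <- data.frame(layout$chrom, layout$start, layout$end, layout$probe_id,
                   0L, ".", layout$array_row, layout$array_col)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tss <- attr(layout, "tss")
  if (!is.null(tss))
    write.table(tss, paste0(path, ".tss.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "probe_id",
                                 "score", "strand", "array_row", "array_col"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character",
                                  "integer", "integer"))
  layout <- df[c("probe_id", "chrom", "start", "end", "array_row", "array_col")]
  layout <- layout[order(layout$chrom, layout$start, layout$probe_id), ]
  rownames(layout) <- NULL
  tss_path <- paste0(path, ".tss.tsv")
  if (file.exists(tss_path))
    attr(layout, "tss") <- read.table(tss_path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  class(layout) <- c("probe_layout", "data.frame")
  layout
}

#' Write / read a signal matrix as TSV
#'
#' First column `probe_id`, one column per sample; the processing stage is
#' kept in a `# stage:` header comment.
#'
#' @param m a `signal_matrix`.
#' @param path output file.
#' @export
write_signal <- function(m, path) {
  stopifnot(inherits(m, "signal_matrix"))
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# stage: ", m$stage), con)
  df <- data.frame(probe_id = m$probe_ids, m$values, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @param layout probe layout the rows must align to.
#' @param sheet sample sheet the columns must align to.
#' @export
read_signal <- function(path, layout, sheet) {
  first <- readLines(path, n = 1)
  stage <- if (startsWith(first, "# stage:")) trimws(sub("# stage:", "", first))
           else "raw"
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  i <- match(layout$probe_id, df$probe_id)
  if (anyNA(i)) stop("signal file is missing probes present in the layout")
  vals <- as.matrix(df[i, sheet$sample_id, drop = FALSE])
  rownames(vals) <- layout$probe_id
  signal_matrix(vals, layout, sheet, stage = stage)
}

#' Write / read DMR regions as BED
#'
#' BED6 with name = direction and score = -10 log10 of the region's best
#' window p-value (capped at 1000).
#'
#' @param regions DMR data.frame (`chrom`, `start`, `end`, `direction`,
#'   optional `n_probes`, `best_p`).
#' @param path output file.
#' @export
write_regions <- function(regions, path) {
  score <- if (!is.null(regions$best_p))
    pmin(1000, round(-10 * log10(pmax(regions$best_p, 1e-100)))) else 0L
  df <- data.frame(regions$chrom, regions$start, regions$end,
                   regions$direction, score, ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$direction <- as.character(df[[4]])
  out
}

#' Write / read a sample sheet TSV
#' @param sheet sample sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character")
  need <- c("sample_id", "genotype", "cell_type")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sheet
}

#' Write a CpG-unit matrix as long-format TSV
#' @param m a `cpg_unit_matrix`.
#' @param path file path.
#' @export
write_cpg_units <- function(m, path) {
  old <- options(digits = 15)
  on.exit(options(old), add = TRUE)
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
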