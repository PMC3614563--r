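#' Validate a segment table
#'
#' One row per called copy-number segment: `sample`, `chrom`, `start`,
#' `end` (genomic, half-open like the exon model), `n_exons`,
#' `mean_log_ratio`, `combined_p` (Fisher's-method segment p-value) and
#' `call` (`del` for negative mean log-ratio, `amp` for positive).
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble of class `segment_table`.
#' @export
segment_table <- function(x) {
  x <- as_tibble(x)
  need <- c("sample", "chrom", "start", "end", "n_exons",
            "mean_log_ratio", "combined_p", "call")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("segment table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x[, need]
  x$sample <- as.character(x$sample)
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$n_exons <- as.integer(x$n_exons)
  x$mean_log_ratio <- as.numeric(x$mean_log_ratio)
  x$combined_p <- as.numeric(x$combined_p)
  x$call <- as.character(x$call)
  if (any(x$start >= x$end)) abort("segment with start >= end")
  if (any(x$n_exons < 1)) abort("segment with n_exons < 1")
  if (!all(x$call %in% c("del", "amp"))) abort("call must be 'del' or 'amp'")
  if (any((x$call == "del") != (x$mean_log_ratio < 0))) {
    abort("call 'del' must coincide with negative mean_log_ratio")
  }
  structure(x, class = c("segment_table", class(tibble())))
}

#' Write a segment table as a SEG file
#'
#' Standard SEG columns (`sample`, `chrom`, `start`, `end`, `num_mark`,
#' `seg_mean`) followed by `combined_p` and `call`. Reading the file back
#' with [read_segments] reproduces the table.
#'
#' @param segments A [segment_table] (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  segments <- segment_table(segments)
  out <- tibble(
    sample = segments$sample, chrom = segments$chrom,
    start = segments$start, end = segments$end,
    num_mark = segments$n_exons, seg_mean = segments$mean_log_ratio,
    combined_p = segments$combined_p, call = segments$call
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a SEG file written by [write_segments]
#'
#' @param path Path to a SEG file.
#' @return A [segment_table].
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample = "c", chrom = "c", start = "i", end = "i",
                           num_mark = "i", seg_mean = "d",
                           combined_p = "d", call = "c"))
  segment_table(dplyr::rename(seg, n_exons = "num_mark",
                              mean_log_ratio = "seg_mean"))
}
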