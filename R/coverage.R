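#' Construct a per-exon coverage matrix
#'
#' Holds read counts per (exon, sample) together with per-sample library
#' totals (total mapped reads, on- plus off-target). Sample order is
#' meaningful: the matched blood sample comes first, tumors follow in
#' biological order (e.g. primary, metastasis, recurrence).
#'
#' @param model An [exon_model].
#' @param counts Matrix or data frame of nonnegative integer counts,
#'   `nrow(model)` rows, one column per sample.
#' @param library_totals Named integer vector of total mapped reads per
#'   sample; each must be at least the corresponding column sum.
#' @param sample_names Optional character vector overriding
#'   `colnames(counts)`.
#'
#' @return A tibble of class `coverage_matrix`: exon columns (`exon_id`,
#'   `chrom`, `start`, `end`) followed by one count column per sample;
#'   attributes `library_totals` and `sample_names`.
#' @export
coverage_matrix <- function(model, counts, library_totals, sample_names = NULL) {
  counts <- as.matrix(counts)
  sample_names <- sample_names %||% colnames(counts)
  if (is.null(sample_names)) abort("counts must have sample names")
  colnames(counts) <- sample_names
  if (nrow(counts) != nrow(model)) {
    abort(sprintf("counts has %d rows but exon model has %d",
                  nrow(counts), nrow(model)))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers")
  }
  library_totals <- library_totals[sample_names]
  if (anyNA(library_totals)) abort("library_totals must name every sample")
  if (any(library_totals <= 0)) abort("library_totals must be positive")
  storage.mode(counts) <- "integer"
  short <- library_totals < colSums(counts)
  if (any(short)) {
    abort(paste0("library total below on-target column sum for sample(s): ",
                 paste(sample_names[short], collapse = ", ")))
  }
  out <- dplyr::bind_cols(as_tibble(model)[, c("exon_id", "chrom", "start", "end")],
                          as_tibble(counts))
  structure(out,
            library_totals = library_totals,
            sample_names = sample_names,
            genome_order = attr(model, "genome_order"),
            class = c("coverage_matrix", class(tibble())))
}

#' Sample names of a coverage matrix
#' @param cov A [coverage_matrix].
#' @return Character vector, blood first.
#' @export
cov_samples <- function(cov) attr(cov, "sample_names")

#' Library totals of a coverage matrix
#' @param cov A [coverage_matrix].
#' @return Named numeric vector of total mapped reads.
#' @export
cov_totals <- function(cov) attr(cov, "library_totals")

#' Read a coverage matrix from a TSV pair
#'
#' The main table is tab-delimited with header
#' `exon_id  chrom  start  end  <sample...>`; the sidecar totals file has
#' columns `sample` and `total_reads`.
#'
#' @param path Path to the count table TSV.
#' @param totals_path Path to the sidecar totals TSV. Defaults to
#'   `<path without extension>.totals.tsv`.
#' @return A [coverage_matrix].
#' @export
read_coverage_matrix <- function(path, totals_path = NULL) {
  totals_path <- totals_path %||% paste0(sub("\\.tsv$", "", path), ".totals.tsv")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("exon_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    abort(paste0("coverage table must start with columns ",
                 paste(need, collapse = ", ")))
  }
  samples <- setdiff(names(tab), need)
  if (length(samples) == 0) abort("coverage table has no sample columns")
  totals <- readr::read_tsv(totals_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "total_reads") %in% names(totals))) {
    abort("totals sidecar must have columns sample, total_reads")
  }
  model <- exon_model(tab[, need])
  coverage_matrix(model, as.matrix(tab[, samples, drop = FALSE]),
                  setNames(totals$total_reads, totals$sample),
                  sample_names = samples)
}

#' Write a coverage matrix to a TSV pair
#'
#' @param cov A [coverage_matrix].
#' @param path Output path for the count table; the totals sidecar is written
#'   next to it as `<path without extension>.totals.tsv`.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(cov, path) {
  readr::write_tsv(as_tibble(cov), path)
  totals <- cov_totals(cov)
  readr::write_tsv(tibble(sample = names(totals), total_reads = unname(totals)),
                   paste0(sub("\\.tsv$", "", path), ".totals.tsv"))
  invisible(path)
}
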