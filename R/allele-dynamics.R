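#' Mutant allele frequency from read counts
#'
#' AF = alt-supporting reads / total reads. Zero depth yields `NA` (no
#' measurement), not an error.
#'
#' @param alt_reads,depth Integer vectors.
#' @return Numeric vector of frequencies in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' allele_frequency(57, 100)
allele_frequency <- function(alt_reads, depth) {
  if (any(alt_reads < 0 | depth < 0, na.rm = TRUE)) {
    abort("negative read counts")
  }
  if (any(alt_reads > depth, na.rm = TRUE)) abort("alt_reads > depth")
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Convert Sanger peak heights to mutant allele frequency
#'
#' The chromatogram allele proportion is `peak_alt / peak_ref` (call it
#' r); the corresponding allele frequency is `1 / (1 + 1/r) = r / (1 + r)`. The
#' limits are handled explicitly: no alt peak gives frequency 0, no ref
#' peak gives frequency 1.
#'
#' @param peak_alt,peak_ref Nonnegative peak heights (vectors).
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
#' @examples
#' proportion_to_frequency(3, 1) # 0.75
proportion_to_frequency <- function(peak_alt, peak_ref) {
  if (any(peak_alt < 0 | peak_ref < 0, na.rm = TRUE)) {
    abort("peak heights must be nonnegative")
  }
  if (any(peak_alt == 0 & peak_ref == 0, na.rm = TRUE)) {
    abort("ref and alt peaks cannot both be zero")
  }
  dplyr::case_when(
    peak_alt == 0 ~ 0,
    peak_ref == 0 ~ 1,
    TRUE ~ (peak_alt / peak_ref) / (1 + peak_alt / peak_ref)
  )
}

#' Allele frequency back to chromatogram allele proportion
#'
#' Algebraic inverse of [proportion_to_frequency]: `f / (1 - f)`.
#'
#' @param f Frequencies in `[0, 1)`; `f = 1` maps to `Inf`.
#' @return Allele proportions.
#' @export
frequency_to_proportion <- function(f) {
  if (any(f < 0 | f > 1, na.rm = TRUE)) abort("frequencies must lie in [0, 1]")
  ifelse(f == 1, Inf, f / (1 - f))
}

#' Build allele-frequency trajectories across ordered samples
#'
#' Collapses per-sample variant records into one row per (variant, sample)
#' with the exome AF, optionally joined with Sanger measurements (either
#' direct frequencies in `af_sanger` or peak heights in
#' `peak_ref`/`peak_alt`, converted via [proportion_to_frequency]).
#'
#' @param variants A variant table (see [variant_records]).
#' @param sample_order Character vector fixing the cohort sample order
#'   (blood first when present).
#' @param sanger Optional tibble keyed by `key` and `sample` with either
#'   `af_sanger` or `peak_ref` and `peak_alt`.
#' @return A tibble of class `frequency_series`: `key`, `sample` (factor
#'   in cohort order), `af_exome`, `af_sanger`.
#' @export
build_frequency_series <- function(variants, sample_order, sanger = NULL) {
  variants <- variant_records(variants)
  out <- tibble(
    key = variant_key(variants),
    sample = variants$sample,
    af_exome = allele_frequency(variants$alt_reads, variants$depth)
  )
  out <- dplyr::summarise(dplyr::group_by(out, .data$key, .data$sample),
                          af_exome = mean(.data$af_exome), .groups = "drop")
  if (!is.null(sanger)) {
    sanger <- as_tibble(sanger)
    if (!"af_sanger" %in% names(sanger)) {
      sanger$af_sanger <- proportion_to_frequency(sanger$peak_alt,
                                                  sanger$peak_ref)
    }
    out <- dplyr::left_join(out, sanger[, c("key", "sample", "af_sanger")],
                            by = c("key", "sample"))
  } else {
    out$af_sanger <- NA_real_
  }
  frequency_series(out, sample_order)
}

#' Coerce a long AF table to a frequency series
#'
#' @param x Tibble with columns `key`, `sample`, `af_exome` and optionally
#'   `af_sanger`.
#' @param sample_order Cohort sample order.
#' @return A `frequency_series` tibble.
#' @export
frequency_series <- function(x, sample_order) {
  x <- as_tibble(x)
  if (!all(c("key", "sample", "af_exome") %in% names(x))) {
    abort("frequency series needs columns key, sample, af_exome")
  }
  if (!"af_sanger" %in% names(x)) x$af_sanger <- NA_real_
  extra <- unique(setdiff(x$sample, sample_order))
  if (length(extra) > 0) {
    abort(paste0("samples outside sample_order: ", paste(extra, collapse = ", ")))
  }
  for (col in c("af_exome", "af_sanger")) {
    bad <- !is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 1)
    if (any(bad)) abort(paste0(col, " outside [0, 1]"))
  }
  x$sample <- factor(x$sample, levels = sample_order)
  x <- dplyr::arrange(x, .data$key, .data$sample)
  structure(x, sample_order = sample_order,
            class = c("frequency_series", class(tibble())))
}

#' Select variants whose allele frequency rises across tumors
#'
#' A variant is selected when its best later-sample AF exceeds the
#' baseline (primary tumor) AF by at least `threshold` — relative by
#' default (`af_later >= af_baseline * (1 + threshold)`), or absolute
#' (`af_later >= af_baseline + threshold`). Samples with missing later
#' measurements are ignored rather than failing.
#'
#' @param series A `frequency_series`.
#' @param baseline Baseline sample name (default `"OV"`).
#' @param later Later samples to compare against (default
#'   `c("OMN", "REC")`).
#' @param threshold Minimum rise (default 0.10).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return The subset of `series` rows belonging to selected variants.
#' @export
select_rising_variants <- function(series, baseline = "OV",
                                   later = c("OMN", "REC"),
                                   threshold = 0.10,
                                   mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (threshold < 0) abort("threshold must be nonnegative")
  wide <- tidyr::pivot_wider(
    dplyr::select(as_tibble(series), "key", "sample", "af_exome"),
    names_from = "sample", values_from = "af_exome")
  if (!baseline %in% names(wide)) {
    abort(paste0("baseline sample absent from series: ", baseline))
  }
  later <- intersect(later, names(wide))
  if (length(later) == 0) abort("no later samples present in series")
  best_later <- do.call(pmax, c(unname(wide[later]), na.rm = TRUE))
  base <- wide[[baseline]]
  sel <- !is.na(base) & !is.na(best_later) &
    if (mode == "relative") best_later >= base * (1 + threshold)
    else best_later >= base + threshold
  keys <- wide$key[sel]
  series[series$key %in% keys, , drop = FALSE]
}

#' Exome vs Sanger allele-frequency concordance
#'
#' Pools `(af_exome, af_sanger)` pairs over all variants and the requested
#' samples (tumor samples by default, i.e. every non-blood sample in the
#' series order), drops pairs with a missing member, and computes the
#' Spearman rank correlation with average ranks for ties; the p-value uses
#' the t approximation on `n_pairs - 2` degrees of freedom.
#'
#' @param series A `frequency_series` with Sanger measurements.
#' @param samples Samples to pool; default all non-blood samples.
#' @param blood Name of the blood sample to exclude when `samples` is NULL.
#' @return An `af_concordance` object: `rho`, `p_value`, `n_pairs`, plus a
#'   per-sample breakdown in `$by_sample`. Supports [tidy()] and
#'   [glance()].
#' @export
concordance <- function(series, samples = NULL, blood = "blood") {
  order <- attr(series, "sample_order") %||% levels(factor(series$sample))
  samples <- samples %||% setdiff(order, blood)
  pool <- series[series$sample %in% samples &
                   !is.na(series$af_exome) & !is.na(series$af_sanger), ,
                 drop = FALSE]
  if (nrow(pool) < 3) abort("fewer than 3 complete exome/Sanger pairs")
  spearman <- function(x, y) {
    n <- length(x)
    rho <- cor(rank(x), rank(y))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
  }
  pooled <- spearman(pool$af_exome, pool$af_sanger)
  by_sample <- dplyr::group_by(pool, sample = as.character(.data$sample))
  by_sample <- dplyr::summarise(
    by_sample,
    rho = if (dplyr::n() >= 3) cor(rank(.data$af_exome),
                                   rank(.data$af_sanger)) else NA_real_,
    n_pairs = dplyr::n(), .groups = "drop")
  structure(list(rho = pooled$rho, p_value = pooled$p,
                 n_pairs = pooled$n, by_sample = by_sample,
                 data = pool),
            class = "af_concordance")
}

#' @exportS3Method base::print
print.af_concordance <- function(x, ...) {
  cat(sprintf(
    "Exome vs Sanger AF concordance: Spearman rho = %.3f (p = %.3g, n = %d pairs)\n",
    x$rho, x$p_value, x$n_pairs))
  invisible(x)
}

#' Estimate tumor purity from clonal somatic allele frequencies
#'
#' For clonal somatic variants in copy-number-neutral regions the expected
#' AF is purity/2, so purity is estimated as twice the median AF, clipped
#' to `[0, 1]`. Supply only copy-neutral somatic variants (filter with CNV
#' calls or simulation truth first).
#'
#' @param series A `frequency_series` (or any tibble with `sample` and
#'   `af_exome`) restricted to copy-neutral clonal somatic variants.
#' @param samples Samples to estimate; default every sample present.
#' @return Tibble with columns `sample`, `pi_hat`, `n_variants`, `method`.
#'   Samples with no usable variants get `NA`.
#' @export
estimate_purity <- function(series, samples = NULL) {
  x <- as_tibble(series)
  samples <- samples %||% as.character(unique(x$sample))
  purrr::map_dfr(samples, function(sm) {
    af <- x$af_exome[as.character(x$sample) == sm & !is.na(x$af_exome)]
    tibble(sample = sm,
           pi_hat = if (length(af) == 0) NA_real_
                    else min(1, max(0, 2 * median(af))),
           n_variants = length(af),
           method = "2 x median AF, copy-neutral clonal")
  })
}

#' Packaged validated allele-frequency trio
#'
#' Mutant allele frequencies of 24 Sanger-validated somatic mutations in a
#' matched ovarian carcinoma cohort — primary tumor (OV), omental
#' metastasis (OMN) and post-therapy recurrence (REC) — measured both by
#' exome sequencing and by Sanger chromatogram peak heights. Ships with
#' the package as a plain-text fixture and feeds the concordance example.
#'
#' @return A `frequency_series` tibble (samples OV, OMN, REC; 24 variants;
#'   Sanger values missing for two indels).
#' @export
validated_trio_af <- function() {
  path <- system.file("extdata", "ovarian_trio_validated_af.tsv",
                      package = "trioexome", mustWork = TRUE)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- tidyr::pivot_longer(wide,
                              cols = tidyr::starts_with("af_"),
                              names_to = c(".value", "sample"),
                              names_pattern = "(af_exome|af_sanger)_(.+)")
  frequency_series(long[, c("key", "gene", "var_class", "sample",
                            "af_exome", "af_sanger")],
                   sample_order = c("OV", "OMN", "REC"))
}
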