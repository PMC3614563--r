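#' Tidy an exome/Sanger concordance result
#'
#' @param x An `af_concordance` from [concordance].
#' @param ... Unused.
#' @return One-row tibble with `rho`, `p_value`, `n_pairs`.
#' @export
tidy.af_concordance <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n_pairs = x$n_pairs)
}

#' @rdname tidy.af_concordance
#' @export
glance.af_concordance <- function(x, ...) tidy(x)

#' Per-sample breakdown of a concordance result
#' @param x An `af_concordance`.
#' @return Tibble with per-sample Spearman rho and pair counts.
#' @export
concordance_by_sample <- function(x) x$by_sample

#' Tidy CNV calls
#'
#' @param x A `cnv_calls` object from [call_cnvs].
#' @param ... Unused.
#' @return The segment table as a plain tibble.
#' @export
tidy.cnv_calls <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' Summarize CNV calls
#'
#' @param x A `cnv_calls` object.
#' @param ... Unused.
#' @return One-row tibble: segment counts by direction, exon totals, and
#'   the most significant combined p-value.
#' @export
glance.cnv_calls <- function(x, ...) {
  tibble(n_segments = nrow(x),
         n_del = sum(x$call == "del"),
         n_amp = sum(x$call == "amp"),
         n_exons = sum(x$n_exons),
         min_combined_p = if (nrow(x)) min(x$combined_p) else NA_real_)
}
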