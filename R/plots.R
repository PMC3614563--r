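#' Plot a per-exon log-ratio track with segment overlay
#'
#' Exon log-ratios along the genome, colored by chromosome, with called
#' segments drawn as horizontal bars at their mean log-ratio (blue
#' deletions, red amplifications) — the per-sample view of a genome-wide
#' copy-number heat map.
#'
#' @param object A `cnv_calls` object from [call_cnvs].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cnv_calls <- function(object, ...) {
  track <- attr(object, "track")
  track <- track[!track$masked & is.finite(track$log_ratio), , drop = FALSE]
  track$idx <- seq_len(nrow(track))
  seg <- as_tibble(as.data.frame(object))
  if (nrow(seg) > 0) {
    seg$idx_start <- purrr::map2_dbl(seg$chrom, seg$start, function(ch, st) {
      min(track$idx[track$chrom == ch & track$start >= st])
    })
    seg$idx_end <- purrr::map2_dbl(seg$chrom, seg$end, function(ch, en) {
      max(track$idx[track$chrom == ch & track$end <= en])
    })
  }
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$idx, y = .data$log_ratio)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$chrom), size = 0.3,
                        alpha = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "exon (genome order)", y = "log2 RPKM ratio (tumor/blood)")
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$idx_start, xend = .data$idx_end,
                   y = .data$mean_log_ratio, yend = .data$mean_log_ratio,
                   color = NULL),
      inherit.aes = FALSE, linewidth = 1.2,
      color = ifelse(seg$call == "del", "blue3", "red3"))
  }
  p + ggplot2::theme_minimal()
}

#' Plot allele-frequency trajectories across ordered samples
#'
#' One line per variant, samples in cohort order — the rising-AF view
#' used to pick variants whose mutant fraction grows from primary tumor
#' to metastasis/recurrence.
#'
#' @param series A `frequency_series`.
#' @param highlight Optional character vector of variant keys to emphasize.
#' @return A ggplot.
#' @export
plot_af_trajectories <- function(series, highlight = NULL) {
  df <- as_tibble(series)
  df$highlight <- if (is.null(highlight)) "all" else
    ifelse(df$key %in% highlight, "selected", "other")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$af_exome,
                                   group = .data$key,
                                   color = .data$highlight)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(
      values = c(all = "grey30", other = "grey70", selected = "red3"),
      guide = if (is.null(highlight)) "none" else "legend") +
    ggplot2::labs(x = NULL, y = "mutant allele frequency (exome)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Scatter of exome vs Sanger allele frequencies
#'
#' @param object An `af_concordance` from [concordance].
#' @param ... Unused.
#' @return A ggplot with the identity line and the pooled Spearman rho in
#'   the subtitle.
#' @export
autoplot.af_concordance <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$af_exome, y = .data$af_sanger,
                               color = .data$sample)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "allele frequency (exome)",
                  y = "allele frequency (Sanger)",
                  subtitle = sprintf("Spearman rho = %.2f (n = %d pairs)",
                                     object$rho, object$n_pairs)) +
    ggplot2::theme_minimal()
}
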