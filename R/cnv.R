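#' RPKM normalization
#'
#' Reads Per Kilobase of exon model per Million mapped reads:
#' `count / (exon_length_bp / 1000) / (library_total / 1e6)`.
#'
#' @param count Read count(s).
#' @param exon_length_bp Exon length(s) in bp (> 0).
#' @param library_total Total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(1000, 1000, 1e8) # 10
rpkm <- function(count, exon_length_bp, library_total) {
  if (any(exon_length_bp <= 0)) abort("exon_length_bp must be positive")
  if (any(library_total <= 0)) abort("library_total must be positive")
  count / (exon_length_bp / 1000) / (library_total / 1e6)
}

#' Segmentation and calling parameters
#'
#' @param alpha Significance level for accepting a changepoint split.
#' @param n_permutations Permutations per split test.
#' @param seed Seed for the permutation RNG.
#' @param min_exons Minimum exons for a reported segment; large-event
#'   focus — small calls are removed during smoothing.
#' @param merge_gap_tolerance Maximum difference in mean log-ratio for
#'   merging adjacent same-sign segments.
#' @param call_threshold Minimum `|mean log-ratio|` for a segment to be
#'   called del/amp.
#' @param mask_threshold Blood read count below which an exon is masked
#'   (ratio denominator too unstable).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(alpha = 0.01, n_permutations = 1000,
                                seed = 1, min_exons = 100,
                                merge_gap_tolerance = 0.2,
                                call_threshold = 0.1,
                                mask_threshold = 10) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (min_exons < 1) abort("min_exons must be >= 1")
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), min_exons = as.integer(min_exons),
                 merge_gap_tolerance = merge_gap_tolerance,
                 call_threshold = call_threshold,
                 mask_threshold = mask_threshold),
            class = "segmentation_params")
}

#' Geary-Hinkley per-exon ratio test
#'
#' Tests, per exon, whether the tumor/blood count ratio is consistent with
#' no copy-number change. With library scaling `s = total_tumor /
#' total_blood`, both counts are put on the blood scale and treated as
#' approximately normal with Poisson variance; the Geary-Hinkley
#' transformation of their ratio `R = n_tumor / (s * n_blood)` is then
#' `t = sqrt(n_blood) * (R - 1) / sqrt(R^2 + 1/s)`, standard normal under
#' the null (so `R = 1` gives `t = 0`), with two-sided p-value
#' `2 * (1 - Phi(|t|))`.
#'
#' @param n_tumor,n_blood Per-exon read counts (vectors).
#' @param total_tumor,total_blood Library totals.
#' @param mask_threshold Blood counts below this yield a masked result
#'   (`NA` t and p).
#' @return Tibble with columns `t_stat`, `p`, `masked`.
#' @export
gh_pvalue <- function(n_tumor, n_blood, total_tumor, total_blood,
                      mask_threshold = 10) {
  if (total_tumor <= 0 || total_blood <= 0) abort("library totals must be positive")
  s <- total_tumor / total_blood
  masked <- n_blood < mask_threshold
  R <- ifelse(masked, NA_real_, n_tumor / (s * n_blood))
  t_stat <- sqrt(n_blood) * (R - 1) / sqrt(R^2 + 1 / s)
  p <- 2 * pnorm(-abs(t_stat))
  tibble(t_stat = ifelse(masked, NA_real_, t_stat),
         p = ifelse(masked, NA_real_, p),
         masked = masked)
}

#' Per-exon RPKM log-ratio track with ratio-test statistics
#'
#' Computes blood and tumor RPKM per exon, the `log2(RPKM_tumor /
#' RPKM_blood)` track, and the Geary-Hinkley statistic and p-value per
#' unmasked exon. Exons whose blood count falls below the mask threshold
#' are masked rather than zero-filled.
#'
#' @param cov A [coverage_matrix].
#' @param blood,tumor Sample names in `cov`.
#' @param params A [segmentation_params] (supplies `mask_threshold`).
#' @return A tibble of class `exon_stats`: exon columns plus
#'   `count_blood`, `count_tumor`, `rpkm_blood`, `rpkm_tumor`,
#'   `log_ratio`, `t_stat`, `p`, `masked`.
#' @export
log_ratio_track <- function(cov, blood, tumor,
                            params = segmentation_params()) {
  samples <- cov_samples(cov)
  for (sm in c(blood, tumor)) {
    if (!sm %in% samples) abort(paste0("sample not in coverage matrix: ", sm))
  }
  tab <- as_tibble(cov)
  totals <- cov_totals(cov)
  len <- tab$end - tab$start
  rb <- rpkm(tab[[blood]], len, totals[[blood]])
  rt <- rpkm(tab[[tumor]], len, totals[[tumor]])
  gh <- gh_pvalue(tab[[tumor]], tab[[blood]], totals[[tumor]],
                  totals[[blood]], mask_threshold = params$mask_threshold)
  lr <- ifelse(gh$masked, NA_real_, log2(rt / rb))
  out <- dplyr::bind_cols(
    tab[, c("exon_id", "chrom", "start", "end")],
    tibble(count_blood = tab[[blood]], count_tumor = tab[[tumor]],
           rpkm_blood = rb, rpkm_tumor = rt, log_ratio = lr),
    gh)
  structure(out, blood = blood, tumor = tumor,
            genome_order = attr(cov, "genome_order"),
            class = c("exon_stats", class(tibble())))
}

# Recursive CBS-style splitting of one chromosome's unmasked log-ratios.
# rows: indices into the track; returns tibble of (row_start, row_end)
# ranges over the *unmasked* row vector.
segment_chromosome <- function(x, params) {
  n <- length(x)
  out <- list()
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 4) {
      out[[length(out) + 1]] <<- c(lo, hi)
      return(invisible())
    }
    res <- cbs_split_pvalue(x[lo:hi], params$n_permutations, params$alpha)
    if (res$p < params$alpha && res$j > res$i &&
        !(res$i == 0 && res$j == len)) {
      i <- res$i; j <- res$j
      if (i > 0) recurse(lo, lo + i - 1)
      recurse(lo + i, lo + j - 1)
      if (j < len) recurse(lo + j, hi)
    } else {
      out[[length(out) + 1]] <<- c(lo, hi)
    }
    invisible()
  }
  recurse(1, n)
  ranges <- do.call(rbind, out)
  ranges[order(ranges[, 1]), , drop = FALSE]
}

#' Segment a log-ratio track into constant-mean runs
#'
#' Circular-binary-segmentation-style recursive splitting per chromosome:
#' each step finds the boundary pair maximizing the two-sample mean-shift
#' statistic on the log-ratios and accepts the split when its seeded
#' permutation p-value falls below `alpha`. The returned segments cover
#' every unmasked, finite-log-ratio exon exactly once.
#'
#' @param track An `exon_stats` tibble from [log_ratio_track].
#' @param params A [segmentation_params].
#' @return Tibble of raw segments: `chrom`, `start`, `end` (genomic),
#'   `n_exons`, `mean_log_ratio`, plus `rows` (list column of track row
#'   indices).
#' @export
segment_track <- function(track, params = segmentation_params()) {
  set.seed(params$seed)
  usable <- !track$masked & is.finite(track$log_ratio)
  chroms <- unique(track$chrom)
  segs <- purrr::map_dfr(chroms, function(ch) {
    rows <- which(track$chrom == ch & usable)
    if (length(rows) == 0) return(tibble())
    ranges <- segment_chromosome(track$log_ratio[rows], params)
    purrr::map_dfr(seq_len(nrow(ranges)), function(k) {
      rr <- rows[ranges[k, 1]:ranges[k, 2]]
      tibble(chrom = ch,
             start = track$start[rr[1]],
             end = track$end[rr[length(rr)]],
             n_exons = length(rr),
             mean_log_ratio = mean(track$log_ratio[rr]),
             rows = list(rr))
    })
  })
  segs
}

#' Smooth raw segments: merge neighbors, drop small and weak calls
#'
#' Adjacent same-chromosome segments whose mean log-ratios share sign and
#' differ by at most `merge_gap_tolerance` are merged
#' (exon-count-weighted mean); merged segments with fewer than `min_exons`
#' exons or `|mean| < call_threshold` are then dropped, and survivors are
#' labeled `del`/`amp` by sign.
#'
#' @param segments Raw segments from [segment_track].
#' @param params A [segmentation_params].
#' @return Tibble of called segments (still without combined p-values):
#'   `chrom`, `start`, `end`, `n_exons`, `mean_log_ratio`, `call`, `rows`.
#' @export
smooth_and_merge <- function(segments, params = segmentation_params()) {
  if (nrow(segments) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_exons = integer(), mean_log_ratio = numeric(),
                  call = character(), rows = list()))
  }
  merged <- purrr::map_dfr(unique(segments$chrom), function(ch) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    acc <- s[1, ]
    out <- list()
    for (k in seq_len(nrow(s))[-1]) {
      same_sign <- sign(acc$mean_log_ratio) == sign(s$mean_log_ratio[k]) &&
        sign(acc$mean_log_ratio) != 0
      close <- abs(acc$mean_log_ratio - s$mean_log_ratio[k]) <=
        params$merge_gap_tolerance
      if (same_sign && close) {
        w <- c(acc$n_exons, s$n_exons[k])
        acc$mean_log_ratio <- sum(w * c(acc$mean_log_ratio,
                                        s$mean_log_ratio[k])) / sum(w)
        acc$end <- s$end[k]
        acc$n_exons <- sum(w)
        acc$rows <- list(c(acc$rows[[1]], s$rows[[k]]))
      } else {
        out[[length(out) + 1]] <- acc
        acc <- s[k, ]
      }
    }
    out[[length(out) + 1]] <- acc
    dplyr::bind_rows(out)
  })
  keep <- merged$n_exons >= params$min_exons &
    abs(merged$mean_log_ratio) >= params$call_threshold
  merged <- merged[keep, , drop = FALSE]
  merged$call <- ifelse(merged$mean_log_ratio < 0, "del", "amp")
  merged
}

#' Combine member-exon p-values with Fisher's method
#'
#' `X = -2 * sum(log(p_i))` over the segment's unmasked exons is
#' chi-square with `2k` degrees of freedom under the joint null; the
#' combined p-value is its upper tail. Underflow is reported as 1e-300
#' rather than 0.
#'
#' @param p Vector of per-exon p-values in `(0, 1]`.
#' @return Combined p-value.
#' @export
#' @examples
#' fisher_combined_p(c(0.1, 0.2, 0.3))
fisher_combined_p <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) abort("no p-values to combine")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p))
  max(pchisq(X, df = 2 * length(p), lower.tail = FALSE), 1e-300)
}

#' Full read-depth CNV calling chain for one tumor
#'
#' RPKM normalization, log-ratio track with per-exon Geary-Hinkley
#' p-values, seeded CBS-style segmentation, smoothing/merging with the
#' large-event filters, and Fisher's-method combined p-value per surviving
#' segment. Deterministic given `params$seed`.
#'
#' @param cov A [coverage_matrix].
#' @param blood,tumor Sample names in `cov`.
#' @param params A [segmentation_params].
#' @return A [segment_table] of class `cnv_calls` (also carries the
#'   per-exon track in attribute `track` for diagnostics/plotting).
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
call_cnvs <- function(cov, blood, tumor, params = segmentation_params()) {
  track <- log_ratio_track(cov, blood, tumor, params)
  raw <- segment_track(track, params)
  called <- smooth_and_merge(raw, params)
  combined_p <- purrr::map_dbl(called$rows,
                               function(rr) fisher_combined_p(track$p[rr]))
  out <- segment_table(tibble(
    sample = tumor, chrom = called$chrom, start = called$start,
    end = called$end, n_exons = called$n_exons,
    mean_log_ratio = called$mean_log_ratio,
    combined_p = if (nrow(called)) combined_p else numeric(0),
    call = called$call))
  structure(out, track = track, params = params,
            class = c("cnv_calls", class(out)))
}

#' @exportS3Method base::print
print.cnv_calls <- function(x, ...) {
  tr <- attr(x, "track")
  cat(sprintf("CNV calls for %s vs %s: %d segment(s)\n",
              attr(tr, "tumor") %||% "tumor",
              attr(tr, "blood") %||% "blood", nrow(x)))
  NextMethod()
}
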