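test_that("RPKM normalization is exact and linear", {
  expect_equal(rpkm(1000, 1000, 1e8), 10)
  expect_equal(rpkm(0, 500, 1e7), 0)
  expect_equal(rpkm(2 * 700, 350, 5e7), 2 * rpkm(700, 350, 5e7))
  expect_equal(rpkm(700, 350, 2 * 5e7), rpkm(700, 350, 5e7) / 2)
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 100, 0), "positive")
})

test_that("the ratio statistic is zero at the null ratio and matches the closed form", {
  null <- gh_pvalue(100, 100, 1e6, 1e6)
  expect_equal(null$t_stat, 0)
  expect_equal(null$p, 1)

  # frozen closed-form example: t = -30 / sqrt(149)
  ex <- gh_pvalue(70, 100, 1e6, 1e6)
  expect_equal(ex$t_stat, -30 / sqrt(149), tolerance = 1e-12)
  expect_equal(ex$p, 2 * pnorm(-30 / sqrt(149)), tolerance = 1e-12)

  # library scaling: the null ratio accounts for the library-size ratio
  scaled <- gh_pvalue(200, 100, 2e6, 1e6)
  expect_equal(scaled$t_stat, 0)
  expect_equal(scaled$p, 1)

  expect_true(gh_pvalue(5, 5, 1e6, 1e6)$masked)
})

test_that("the transformed statistic matches the normal-ratio tail by simulation", {
  # Monte-Carlo oracle: X, Y ~ Normal(100, 100); the empirical probability
  # of X/Y <= 0.7 should match Phi(t) for the t at ratio 0.7
  set.seed(41)
  n <- 2e5
  X <- rnorm(n, 100, 10); Y <- rnorm(n, 100, 10)
  emp <- mean(X / Y <= 0.7)
  t <- gh_pvalue(70, 100, 1e6, 1e6)$t_stat
  se <- sqrt(emp * (1 - emp) / n)
  expect_lt(abs(emp - pnorm(t)), 4 * se + 1e-4)
})

test_that("deviation symmetry flips t and preserves p", {
  nb <- 144
  for (R in c(1.3, 2, 4.7)) {
    up <- gh_pvalue(nb * R, nb, 1e6, 1e6)
    down <- gh_pvalue(nb / R, nb, 1e6, 1e6)
    expect_equal(up$t_stat, -down$t_stat, tolerance = 1e-6)
    expect_equal(up$p, down$p, tolerance = 1e-6)
  }
})

test_that("|t| grows with the count deviation at fixed blood depth", {
  tumor <- c(100, 110, 130, 160, 200, 260)
  t <- abs(gh_pvalue(tumor, rep(100, 6), 1e6, 1e6)$t_stat)
  expect_true(all(diff(t) > 0))
  tumor_dn <- c(100, 90, 70, 50, 30)
  t_dn <- abs(gh_pvalue(tumor_dn, rep(100, 5), 1e6, 1e6)$t_stat)
  expect_true(all(diff(t_dn) > 0))
})

test_that("Fisher's method matches its chi-square definition", {
  # k = 1 is the identity; all ones combine to one
  expect_equal(fisher_combined_p(0.5), 0.5)
  expect_equal(fisher_combined_p(rep(1, 7)), 1)

  # numerical-integration oracle for the chi-square upper tail, 2k df
  chisq_tail <- function(X, df) {
    stats::integrate(function(u) u^(df / 2 - 1) * exp(-u / 2) /
                       (2^(df / 2) * gamma(df / 2)),
                     lower = X, upper = Inf, rel.tol = 1e-10)$value
  }
  p <- c(0.1, 0.2, 0.3)
  X <- -2 * sum(log(p))
  expect_equal(X, 10.231992, tolerance = 1e-6)
  expect_equal(fisher_combined_p(p), chisq_tail(X, 6), tolerance = 1e-8)

  # exact arithmetic identity on random inputs
  set.seed(2)
  for (k in c(2, 5, 40)) {
    q <- runif(k)
    expect_identical(fisher_combined_p(q),
                     pchisq(-2 * sum(log(q)), 2 * k, lower.tail = FALSE))
  }
  # underflow floors at 1e-300 and invalid inputs error
  expect_equal(fisher_combined_p(rep(1e-12, 50)), 1e-300)
  expect_error(fisher_combined_p(c(0.5, 0)), "\\(0, 1\\]")
})

flat_track <- function(x, chrom = "chr1") {
  n <- length(x)
  start <- seq(0L, by = 1000L, length.out = n)
  structure(tibble::tibble(
    exon_id = sprintf("e%04d", seq_len(n)), chrom = chrom,
    start = start, end = start + 200L,
    count_blood = 100L, count_tumor = 100L,
    rpkm_blood = 1, rpkm_tumor = 1,
    log_ratio = x, t_stat = 0, p = runif(n), masked = FALSE),
    class = c("exon_stats", class(tibble::tibble())))
}

test_that("segmentation finds no changepoint in flat noise", {
  set.seed(51)
  track <- flat_track(rnorm(500, 0, 0.1))
  segs <- segment_track(track, segmentation_params(seed = 1))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_exons, 500L)
})

test_that("segmentation localizes a planted step within a few exons", {
  set.seed(52)
  x <- c(rnorm(200, 0, 0.1), rnorm(200, -0.5, 0.1))
  segs <- segment_track(flat_track(x), segmentation_params(seed = 2))
  expect_equal(nrow(segs), 2L)
  expect_lt(abs(segs$n_exons[1] - 200L), 4L)
  expect_equal(sum(segs$n_exons), 400L)
  expect_lt(abs(segs$mean_log_ratio[2] + 0.5), 0.05)
})

test_that("segmentation partitions unmasked exons exhaustively without overlap", {
  set.seed(53)
  x <- c(rnorm(150, 0, 0.15), rnorm(120, 0.6, 0.15), rnorm(150, 0, 0.15))
  track <- flat_track(x)
  track$masked[sample.int(420, 25)] <- TRUE
  track$log_ratio[track$masked] <- NA
  segs <- segment_track(track, segmentation_params(seed = 3))
  rows <- sort(unlist(segs$rows))
  expect_identical(rows, which(!track$masked))
  expect_equal(anyDuplicated(rows), 0L)
  expect_equal(sum(segs$n_exons), sum(!track$masked))
})

test_that("smoothing merges close same-sign neighbors and drops weak or small calls", {
  raw <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 1000L, 2000L, 3000L),
    end = c(999L, 1999L, 2999L, 3999L),
    n_exons = c(150L, 150L, 50L, 400L),
    mean_log_ratio = c(-0.50, -0.55, -0.52, 0.02),
    rows = list(1:150, 151:300, 301:350, 351:750))
  out <- smooth_and_merge(raw, segmentation_params(min_exons = 100))
  # the three deletions merge (weighted mean), the flat tail is dropped
  expect_equal(nrow(out), 1L)
  expect_equal(out$call, "del")
  expect_equal(out$n_exons, 350L)
  expect_equal(out$mean_log_ratio,
               sum(c(150, 150, 50) * c(-0.50, -0.55, -0.52)) / 350)

  # opposite signs never merge, however close
  raw2 <- raw[1:2, ]
  raw2$mean_log_ratio <- c(-0.5, 0.5)
  out2 <- smooth_and_merge(raw2, segmentation_params(min_exons = 100))
  expect_equal(out2$call, c("del", "amp"))

  # a lone small segment is removed
  raw3 <- raw[3, ]
  out3 <- smooth_and_merge(raw3, segmentation_params(min_exons = 100))
  expect_equal(nrow(out3), 0L)

  # distant same-sign means stay separate
  raw4 <- raw[1:2, ]
  raw4$mean_log_ratio <- c(-0.2, -0.9)
  out4 <- smooth_and_merge(raw4, segmentation_params(min_exons = 100))
  expect_equal(nrow(out4), 2L)
})

test_that("the full caller recovers planted segments and stays silent on null data", {
  co <- simulate_cohort(recovery_config(seed = 61))
  calls <- call_cnvs(co$coverage, "blood", "T1",
                     segmentation_params(seed = 7))
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$call, c("del", "amp"))
  truth <- truth_rows(co$model, co$truth$segments)
  for (k in 1:2) {
    seg <- co$truth$segments[k, ]
    got <- calls[calls$chrom == seg$chrom, ]
    expect_equal(nrow(got), 1L)
    called_rows <- which(co$model$chrom == got$chrom &
                           co$model$start >= got$start &
                           co$model$end <= got$end)
    overlap <- length(intersect(called_rows, truth[[k]])) /
      length(truth[[k]])
    expect_gte(overlap, 0.95)
  }

  null_calls <- call_cnvs(make_null_cohort(8000, 150, seed = 62),
                          "blood", "tumor", segmentation_params(seed = 8))
  expect_equal(nrow(null_calls), 0L)
})

test_that("higher purity magnifies the recovered log-ratios", {
  cfg <- recovery_config(seed = 63, purity = c(lowp = 0.4, highp = 0.85))
  co <- simulate_cohort(cfg)
  low <- call_cnvs(co$coverage, "blood", "lowp",
                   segmentation_params(seed = 9))
  high <- call_cnvs(co$coverage, "blood", "highp",
                    segmentation_params(seed = 10))
  expect_equal(nrow(high), 2L)
  for (ch in unique(high$chrom)) {
    hi <- high$mean_log_ratio[high$chrom == ch]
    lo <- low$mean_log_ratio[low$chrom == ch]
    if (length(lo) == 1) expect_gt(abs(hi), abs(lo))
  }
  # the purer tumor sits near the mixing-model expectation
  del <- high[high$call == "del", ]
  expect_equal(del$mean_log_ratio, expected_log_ratio(1, 0.85),
               tolerance = 0.08)
})
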