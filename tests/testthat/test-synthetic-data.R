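test_that("cohorts are reproducible from the seed and differ across seeds", {
  cfg <- simulation_config(n_exons = 2000, n_chrom = 4, seed = 5,
                           truth_segments = tibble::tibble(
                             chrom = "chr2", start_exon = 101L,
                             end_exon = 300L, copy_number = 1L))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(tibble::as_tibble(a$coverage), tibble::as_tibble(b$coverage))
  expect_identical(a$variants, b$variants)
  cfg$seed <- 6L
  c <- simulate_cohort(cfg)
  expect_false(identical(tibble::as_tibble(a$coverage),
                         tibble::as_tibble(c$coverage)))
})

test_that("empirical mean depth matches the configured depth within 2%", {
  cfg <- simulation_config(
    n_exons = 10000, n_chrom = 10,
    truth_segments = tibble::tibble(chrom = character(),
                                    start_exon = integer(),
                                    end_exon = integer(),
                                    copy_number = integer()),
    germline_het_count = 0, rare_germline_count = 0,
    somatic_neutral_count = 0, somatic_in_cnv_count = 0,
    noise_variant_count = 0, seed = 11)
  co <- simulate_cohort(cfg)
  counts <- as.matrix(tibble::as_tibble(co$coverage)[, cov_samples(co$coverage)])
  rel_err <- abs(colMeans(counts) - cfg$mean_depth) / cfg$mean_depth
  expect_true(all(rel_err < 0.02))
})

test_that("truth expectations follow the purity mixing model", {
  # CN = c at purity pi: expected log2 ratio log2(((1-pi)*2 + pi*c)/2)
  expect_equal(expected_log_ratio(2, 0.7), 0)
  expect_equal(expected_log_ratio(1, 1), -1)
  expect_equal(expected_log_ratio(1, 0.6), log2(0.7))
  # somatic AF pi/2 in diploid regions, pi/(2-pi) on the retained allele
  expect_equal(expected_af(0.6), 0.3)
  expect_equal(expected_af(0.6, cn = 1, alt_in_tumor = 1), 0.6 / (2 - 0.6))
  expect_equal(expected_af(1, cn = 1, alt_in_tumor = 1), 1)

  cfg <- simulation_config(n_exons = 2000, n_chrom = 4, seed = 2,
                           purity = c(OV = 0.4, OMN = 0.85, REC = 0.9),
                           truth_segments = tibble::tibble(
                             chrom = "chr2", start_exon = 101L,
                             end_exon = 400L, copy_number = 1L))
  co <- simulate_cohort(cfg)
  seg <- co$truth$segments
  expect_equal(seg$expected_log_ratio_OMN, expected_log_ratio(1, 0.85))
  som <- co$truth$variants[co$truth$variants$type == "somatic_neutral", ]
  expect_true(all(som$expected_af_OMN == 0.85 / 2))
  loss <- co$truth$variants[co$truth$variants$type == "somatic_in_cnv", ]
  expect_true(all(loss$expected_af_OMN == 0.85 / (2 - 0.85)))
})

test_that("zero purity gives a copy-neutral cohort", {
  cfg <- simulation_config(n_exons = 4000, n_chrom = 4, seed = 3,
                           mean_depth = c(blood = 150, T1 = 150),
                           purity = c(T1 = 0),
                           truth_segments = tibble::tibble(
                             chrom = "chr1", start_exon = 1L,
                             end_exon = 1000L, copy_number = 1L),
                           germline_het_count = 0, rare_germline_count = 0,
                           somatic_neutral_count = 0,
                           somatic_in_cnv_count = 0,
                           noise_variant_count = 0)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$segments$expected_log_ratio_T1 == 0))
  tab <- tibble::as_tibble(co$coverage)
  expect_equal(mean(tab$T1) / mean(tab$blood), 1, tolerance = 0.02)
})

test_that("a CN=1 segment at purity 0.6 recovers the attenuated log-ratio", {
  cfg <- simulation_config(
    n_exons = 200000, n_chrom = 20,
    mean_depth = c(blood = 174, T1 = 150), purity = c(T1 = 0.6),
    truth_segments = tibble::tibble(chrom = "chr1", start_exon = 1L,
                                    end_exon = 10000L, copy_number = 1L),
    germline_het_count = 0, rare_germline_count = 0,
    somatic_neutral_count = 0, somatic_in_cnv_count = 0,
    noise_variant_count = 0, seed = 21)
  co <- simulate_cohort(cfg)
  track <- log_ratio_track(co$coverage, "blood", "T1")
  rows <- truth_rows(co$model, co$truth$segments)[[1]]
  m <- mean(track$log_ratio[rows], na.rm = TRUE)
  expect_equal(m, log2(0.7), tolerance = 0.02 / abs(log2(0.7)))
})

test_that("null cohorts are centered and the per-exon test is calibrated", {
  cov <- make_null_cohort(10000, mean_depth = 150, seed = 8)
  cov2 <- make_null_cohort(10000, mean_depth = 150, seed = 8)
  expect_identical(tibble::as_tibble(cov), tibble::as_tibble(cov2))
  track <- log_ratio_track(cov, "blood", "tumor")
  lr <- track$log_ratio[!track$masked]
  expect_lt(abs(mean(lr)), 3 * sd(lr) / sqrt(length(lr)))
  frac <- mean(track$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.05 - 2 * sqrt(0.05 * 0.95 / length(lr)) - 0.006)
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / length(lr)) + 0.006)
})

test_that("planted allele frequencies match their truth within binomial bounds", {
  cfg <- simulation_config(n_exons = 4000, n_chrom = 4, seed = 13,
                           germline_het_count = 40,
                           noise_variant_count = 0)
  co <- simulate_cohort(cfg)
  truth <- co$truth$variants
  v <- co$variants
  v$key <- variant_key(v)
  joined <- dplyr::inner_join(
    v, tidyr::pivot_longer(truth, tidyr::starts_with("expected_af_"),
                           names_to = "sample", values_to = "expected",
                           names_prefix = "expected_af_"),
    by = c("key", "sample"))
  joined <- joined[joined$depth >= 100, ]
  # 95% binomial band per observation; allow the expected few misses
  z <- 1.96
  se <- sqrt(joined$expected * (1 - joined$expected) / joined$depth)
  inside <- abs(joined$alt_reads / joined$depth - joined$expected) <= z * se + 1e-9
  expect_gt(mean(inside), 0.90)

  # germline blood AF at high depth concentrates near 0.5
  blood_het <- joined[joined$sample == "blood" & joined$expected == 0.5, ]
  expect_gt(mean(blood_het$alt_reads / blood_het$depth >= 0.40 &
                   blood_het$alt_reads / blood_het$depth <= 0.60), 0.95)
})

test_that("misplaced truth segments are rejected", {
  expect_error(
    simulation_config(truth_segments = tibble::tibble(
      chrom = c("chr1", "chr1"), start_exon = c(1L, 50L),
      end_exon = c(100L, 120L), copy_number = c(1L, 3L))),
    "overlap")
  cfg <- simulation_config(n_exons = 100, n_chrom = 2, seed = 1,
                           germline_het_count = 5, rare_germline_count = 0,
                           somatic_neutral_count = 0,
                           somatic_in_cnv_count = 0, noise_variant_count = 0,
                           truth_segments = tibble::tibble(
                             chrom = "chr1", start_exon = 1L,
                             end_exon = 500L, copy_number = 1L))
  expect_error(simulate_cohort(cfg), "exceeds")
})
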