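#' Configure an end-to-end pipeline run
#'
#' A run is backed either by a [simulation_config] (synthetic cohort) or
#' by input files (coverage matrix TSV pair, variant table, optional
#' blacklist). The sample ordering is taken from the coverage matrix:
#' blood first, tumors in biological order; the alt-support quality rule
#' defaults to the first tumor (the primary).
#'
#' @param simulation A [simulation_config], or NULL when using files.
#' @param coverage_path,variants_path,blacklist_path Input files for a
#'   file-backed run.
#' @param criteria A [quality_criteria]; `alt_support_samples` defaults to
#'   the primary tumor at run time when left NULL.
#' @param rising_threshold,rising_mode Passed to
#'   [select_rising_variants].
#' @param seg_params A [segmentation_params].
#' @param min_blood_reads Passed to [call_somatic].
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param out_dir Output directory (created); NULL writes nothing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            coverage_path = NULL, variants_path = NULL,
                            blacklist_path = NULL,
                            criteria = NULL,
                            rising_threshold = 0.10,
                            rising_mode = "relative",
                            seg_params = segmentation_params(),
                            min_blood_reads = 1,
                            seed = 1, out_dir = NULL) {
  if (is.null(simulation) &&
      (is.null(coverage_path) || is.null(variants_path))) {
    abort("either a simulation config or input paths must be given")
  }
  structure(list(simulation = simulation, coverage_path = coverage_path,
                 variants_path = variants_path,
                 blacklist_path = blacklist_path, criteria = criteria,
                 rising_threshold = rising_threshold,
                 rising_mode = rising_mode, seg_params = seg_params,
                 min_blood_reads = min_blood_reads,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 131 + k * 10007) %% 2147483647)
}

#' Run the full matched-cohort analysis
#'
#' Stages: cohort ingestion or simulation; quality filtering;
#' functional/rarity filtering; somatic calling by blood subtraction;
#' allele-frequency trajectories with rising-variant selection; purity
#' estimation from copy-neutral somatic variants; and per-tumor read-depth
#' CNV calling. Re-running with the same config and seed reproduces every
#' output byte for byte.
#'
#' @param config A [pipeline_config].
#' @return A `run_report`: per-stage per-sample record counts, rising
#'   variant keys, purity estimates, CNV summaries and calls, the config
#'   hash and the seed. When `config$out_dir` is set, stage tables are
#'   also written there as TSV/SEG files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  blacklist <- NULL
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- child_seed(config$seed, 1)
    cohort <- simulate_cohort(sim)
    coverage <- cohort$coverage
    variants <- cohort$variants
    truth <- cohort$truth
  } else {
    coverage <- read_coverage_matrix(config$coverage_path)
    variants <- read_variant_table(config$variants_path)
    if (!is.null(config$blacklist_path)) {
      blacklist <- read_blacklist(config$blacklist_path)
    }
  }
  samples <- cov_samples(coverage)
  blood <- samples[1]
  tumors <- samples[-1]
  criteria <- config$criteria %||%
    quality_criteria(alt_support_samples = tumors[1])

  count_by_sample <- function(v) {
    tibble(sample = samples,
           n = unname(vapply(samples, function(sm) sum(v$sample == sm), 0L)))
  }
  qual_filtered <- apply_quality_filters(variants, criteria,
                                         check_samples = FALSE)
  rare <- filter_functional_rare(qual_filtered, blacklist)
  somatic <- call_somatic(rare[rare$sample %in% tumors, , drop = FALSE],
                          variants[variants$sample == blood, , drop = FALSE],
                          min_blood_reads = config$min_blood_reads)
  counts <- dplyr::bind_rows(
    dplyr::mutate(count_by_sample(variants), stage = "raw"),
    dplyr::mutate(count_by_sample(qual_filtered), stage = "quality"),
    dplyr::mutate(count_by_sample(rare), stage = "rare_functional"),
    dplyr::mutate(count_by_sample(somatic), stage = "somatic"))

  series <- build_frequency_series(somatic, sample_order = tumors)
  rising <- tryCatch(
    select_rising_variants(series, baseline = tumors[1],
                           later = setdiff(tumors, tumors[1]),
                           threshold = config$rising_threshold,
                           mode = config$rising_mode),
    error = function(e) series[0, , drop = FALSE])

  cnv <- purrr::map(setNames(tumors, tumors), function(tm) {
    params <- config$seg_params
    params$seed <- child_seed(config$seed, 2 + match(tm, tumors))
    call_cnvs(coverage, blood, tm, params)
  })

  in_called_segment <- function(keys, calls) {
    pos <- strsplit(keys, ":", fixed = TRUE)
    vapply(pos, function(pp) {
      p <- as.integer(pp[2])
      any(calls$chrom == pp[1] & calls$start < p & p <= calls$end)
    }, TRUE)
  }
  neutral <- purrr::map_dfr(tumors, function(tm) {
    s <- series[as.character(series$sample) == tm, , drop = FALSE]
    if (nrow(s) == 0) return(s)
    s[!in_called_segment(s$key, cnv[[tm]]), , drop = FALSE]
  })
  purity <- estimate_purity(neutral, samples = tumors)

  report <- structure(list(
    counts = counts,
    samples = samples,
    rising_keys = unique(rising$key),
    purity = purity,
    cnv_summary = purrr::map_dfr(tumors, function(tm)
      dplyr::mutate(glance(cnv[[tm]]), sample = tm, .before = 1)),
    cnv = purrr::map(cnv, tidy),
    series = series,
    truth = truth,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    version = as.character(utils::packageVersion("trioexome"))
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_coverage_matrix(coverage, out("coverage.tsv"))
    write_variant_table(variants, out("variants_raw.tsv"))
    write_variant_table(somatic, out("variants_somatic.tsv"))
    readr::write_tsv(as_tibble(series), out("af_trajectories.tsv"))
    for (tm in tumors) {
      write_segments(cnv[[tm]], out(paste0("cnv_", tm, ".seg")))
    }
    readr::write_tsv(report_table1(report), out("variant_counts.tsv"))
    readr::write_tsv(purity, out("purity.tsv"))
  }
  report
}

#' Per-sample filter-chain counts
#'
#' Wide table of record counts per sample along the filter chain (raw,
#' quality-checked, rare/functional, somatic) — the run's headline
#' bookkeeping table.
#'
#' @param report A `run_report` from [run_pipeline].
#' @return Tibble with one row per sample and one column per stage, in
#'   chain order.
#' @export
report_table1 <- function(report) {
  wide <- tidyr::pivot_wider(report$counts, names_from = "stage",
                             values_from = "n")
  wide <- wide[match(report$samples, wide$sample),
               c("sample", "raw", "quality", "rare_functional", "somatic")]
  wide
}

#' @exportS3Method base::print
print.run_report <- function(x, ...) {
  cat("Matched-cohort exome analysis run (seed", x$seed, ")\n")
  cat("Config hash:", x$config_hash, "\n\nVariant counts by stage:\n")
  print(report_table1(x))
  cat("\nPurity estimates:\n")
  print(x$purity)
  cat("\nCNV summary:\n")
  print(x$cnv_summary)
  cat("\nRising variants:", length(x$rising_keys), "\n")
  invisible(x)
}
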