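#' Configuration for a simulated matched-tumor cohort
#'
#' Defines a blood + multi-tumor exome cohort with known copy-number truth,
#' tumor purity and planted variants. Defaults emulate a matched ovarian
#' carcinoma trio: blood at 174x mean depth and primary/metastasis/
#' recurrence (OV/OMN/REC) at 130x/162x/146x, with tumor purities 0.4,
#' 0.85 and 0.9 — the primary carries substantial normal-tissue admixture,
#' so its copy-number log-ratios and somatic allele frequencies are
#' attenuated relative to the purer later tumors.
#'
#' @param n_exons Number of exons in the simulated capture design.
#' @param n_chrom Number of chromosomes the exons are spread over.
#' @param exon_length_bp Exon length in bp; scalar or vector of `n_exons`.
#' @param mean_depth Named per-sample expected read count per exon; the
#'   first entry is the matched blood sample.
#' @param purity Named per-tumor purity in `[0, 1]` (fraction of malignant
#'   cells); names must match the tumor entries of `mean_depth`.
#' @param truth_segments Tibble of true copy-number segments with columns
#'   `chrom`, `start_exon`, `end_exon` (1-based indices into the exons of
#'   that chromosome, inclusive) and `copy_number` (integer; 2 = neutral).
#'   Default: one 400-exon single-copy deletion and one 400-exon
#'   single-copy amplification, each a small fraction of the exome as
#'   arm-level events are of a real capture design.
#' @param germline_het_count Common germline heterozygous sites (known in
#'   population databases); sites falling in deletion truth undergo LOH.
#' @param rare_germline_count Rare functional germline variants (absent
#'   from databases), e.g. an inherited predisposition allele.
#' @param somatic_neutral_count Clonal somatic variants planted in
#'   copy-number-neutral regions (expected AF = purity/2).
#' @param somatic_in_cnv_count Clonal somatic variants planted inside the
#'   first deletion truth segment on the retained allele
#'   (expected AF = purity/(2 - purity)).
#' @param noise_variant_count Low-quality single-sample artifact calls that
#'   the quality filters are expected to remove.
#' @param overdispersion Standard deviation (log scale) of the lognormal
#'   per-exon capture-efficiency multiplier shared by all samples.
#' @param on_target_rate Fraction of the library mapping to the exon model;
#'   library totals include the off-target remainder.
#' @param loh_lost_allele Which allele deletions remove at germline
#'   heterozygous sites: `"ref"` (mutant allele retained, AF rises) or
#'   `"alt"`.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_exons = 20000,
                              n_chrom = 20,
                              exon_length_bp = 200,
                              mean_depth = c(blood = 174, OV = 130,
                                             OMN = 162, REC = 146),
                              purity = c(OV = 0.4, OMN = 0.85, REC = 0.9),
                              truth_segments = NULL,
                              germline_het_count = 60,
                              rare_germline_count = 2,
                              somatic_neutral_count = 20,
                              somatic_in_cnv_count = 5,
                              noise_variant_count = 150,
                              overdispersion = 0.3,
                              on_target_rate = 0.5,
                              loh_lost_allele = c("ref", "alt"),
                              seed = 1) {
  loh_lost_allele <- match.arg(loh_lost_allele)
  if (is.null(names(mean_depth)) || any(!nzchar(names(mean_depth)))) {
    abort("mean_depth must be a named vector, blood first")
  }
  if (any(mean_depth <= 0)) abort("mean_depth must be positive")
  tumors <- names(mean_depth)[-1]
  if (!setequal(names(purity), tumors)) {
    abort("purity must name exactly the tumor samples of mean_depth")
  }
  if (any(purity < 0 | purity > 1)) abort("purity must lie in [0, 1]")
  if (overdispersion < 0) abort("overdispersion must be nonnegative")
  if (is.null(truth_segments)) {
    # one arm-level deletion and one amplification on distinct chromosomes
    # (the canonical 17p/17q loss and 8q gain when the design has them)
    per_chrom <- n_exons %/% n_chrom
    ch_del <- min(17L, n_chrom)
    ch_amp <- if (n_chrom >= 8 && ch_del != 8L) 8L else max(1L, ch_del - 1L)
    start <- max(1L, per_chrom %/% 4L)
    end <- min(per_chrom, start + 399L)
    truth_segments <- tibble(
      chrom = paste0("chr", c(ch_del, ch_amp)),
      start_exon = c(start, start),
      end_exon = c(end, end),
      copy_number = c(1L, 3L)
    )
    if (ch_del == ch_amp) truth_segments <- truth_segments[1, ]
  }
  truth_segments <- as_tibble(truth_segments)
  split_check <- dplyr::group_by(truth_segments, .data$chrom)
  overlap <- dplyr::summarise(
    split_check,
    bad = {
      o <- order(.data$start_exon)
      any(head(.data$end_exon[o], -1) >= tail(.data$start_exon[o], -1))
    })
  if (any(overlap$bad)) abort("truth segments overlap within a chromosome")
  if (any(truth_segments$start_exon > truth_segments$end_exon)) {
    abort("truth segment with start_exon > end_exon")
  }
  if (any(truth_segments$copy_number < 0)) abort("negative copy number")
  structure(list(
    n_exons = as.integer(n_exons), n_chrom = as.integer(n_chrom),
    exon_length_bp = exon_length_bp, mean_depth = mean_depth,
    purity = purity[tumors], truth_segments = truth_segments,
    germline_het_count = germline_het_count,
    rare_germline_count = rare_germline_count,
    somatic_neutral_count = somatic_neutral_count,
    somatic_in_cnv_count = somatic_in_cnv_count,
    noise_variant_count = noise_variant_count,
    overdispersion = overdispersion, on_target_rate = on_target_rate,
    loh_lost_allele = loh_lost_allele, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Expected log2 copy-number ratio at a given purity
#'
#' A segment at integer copy number `cn` in a tumor of purity `pi` mixes
#' malignant cells (`cn` copies) with normal cells (2 copies), so its
#' expected read-depth log-ratio is `log2(((1 - pi) * 2 + pi * cn) / 2)`.
#'
#' @param cn Copy number (vector).
#' @param purity Tumor purity in `[0, 1]`.
#' @return Expected log2 ratio.
#' @export
#' @examples
#' expected_log_ratio(1, 0.6) # about -0.515
expected_log_ratio <- function(cn, purity) {
  log2(((1 - purity) * 2 + purity * cn) / 2)
}

# Alt-allele copy count in malignant cells for a variant at copy number cn.
# `on_kept` means the variant sits on the retained (deletion) or amplified
# (gain) allele.
alt_copies <- function(cn, germline, on_kept) {
  if (cn == 2) return(1)
  if (cn < 2) {
    if (on_kept) cn else 0
  } else {
    if (on_kept) cn - 1 else 1
  }
}

#' Expected variant allele frequency under purity and copy number
#'
#' @param purity Tumor purity.
#' @param cn Copy number of the surrounding segment in malignant cells.
#' @param alt_in_tumor Alt-allele copies per malignant cell.
#' @param alt_in_normal Alt-allele copies per normal cell (1 for a germline
#'   heterozygote, 0 for a somatic variant).
#' @return Expected allele frequency.
#' @export
expected_af <- function(purity, cn = 2, alt_in_tumor = 1, alt_in_normal = 0) {
  ((1 - purity) * alt_in_normal + purity * alt_in_tumor) /
    ((1 - purity) * 2 + purity * cn)
}

build_sim_exon_model <- function(config) {
  per_chrom <- rep(config$n_exons %/% config$n_chrom, config$n_chrom)
  per_chrom[config$n_chrom] <- per_chrom[config$n_chrom] +
    config$n_exons %% config$n_chrom
  len <- rep_len(config$exon_length_bp, config$n_exons)
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len))
  start <- (idx_in_chrom - 1L) * as.integer(round(max(len) + 800))
  exon_model(tibble(chrom = chrom, start = start,
                    end = start + as.integer(round(len)),
                    exon_id = sprintf("exon_%06d", seq_len(config$n_exons))))
}

# Copy-number matrix (exon x tumor) from truth segments.
cn_matrix <- function(model, config) {
  tumors <- names(config$purity)
  cn <- matrix(2L, nrow = nrow(model), ncol = length(tumors),
               dimnames = list(NULL, tumors))
  for (k in seq_len(nrow(config$truth_segments))) {
    seg <- config$truth_segments[k, ]
    rows <- which(model$chrom == seg$chrom)
    if (length(rows) < seg$end_exon) {
      abort(sprintf("truth segment on %s exceeds its %d exons",
                    seg$chrom, length(rows)))
    }
    cn[rows[seg$start_exon:seg$end_exon], ] <- seg$copy_number
  }
  cn
}

#' Simulate a matched blood + multi-tumor exome cohort
#'
#' Per-exon counts are drawn as `Poisson(mean_depth * g * dosage)`, where
#' `g` is a lognormal capture-efficiency multiplier shared across samples
#' (it cancels in tumor/blood ratios, as shared capture bias does in real
#' matched designs) and `dosage = ((1 - purity) * 2 + purity * cn) / 2`.
#' Library totals are the on-target column sums plus an off-target
#' component computed from the diploid expectation, since off-target
#' coverage is genome-wide and essentially unaffected by focal CNVs.
#' Germline heterozygous alt counts are Binomial(depth, 0.5) in blood and
#' purity/copy-number adjusted in tumors (LOH inside deletion truth);
#' somatic alt counts are Binomial with the [expected_af] of their context.
#'
#' @param config A [simulation_config].
#' @return A list of class `sim_cohort` with elements `model`
#'   ([exon_model]), `coverage` ([coverage_matrix]), `variants` (variant
#'   tibble, see [variant_records]) and `truth` (a `truth_set`: `segments`
#'   with expected log-ratios per tumor, `variants` with expected AF per
#'   sample, `purities`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  model <- build_sim_exon_model(config)
  n <- nrow(model)
  samples <- names(config$mean_depth)
  blood <- samples[1]
  tumors <- samples[-1]
  sd_g <- config$overdispersion
  g <- exp(rnorm(n, -sd_g^2 / 2, sd_g))
  cn <- cn_matrix(model, config)
  counts <- matrix(0L, nrow = n, ncol = length(samples),
                   dimnames = list(NULL, samples))
  counts[, blood] <- rpois(n, config$mean_depth[blood] * g)
  for (tm in tumors) {
    dosage <- ((1 - config$purity[tm]) * 2 + config$purity[tm] * cn[, tm]) / 2
    counts[, tm] <- rpois(n, config$mean_depth[tm] * g * dosage)
  }
  off_target <- round(n * config$mean_depth *
                        (1 / config$on_target_rate - 1))
  totals <- colSums(counts) + off_target[samples]
  coverage <- coverage_matrix(model, counts, totals, sample_names = samples)

  truth_segments <- dplyr::mutate(
    config$truth_segments,
    !!!setNames(
      purrr::map(names(config$purity),
                 function(tm) rlang::quo(
                   expected_log_ratio(.data$copy_number, config$purity[[tm]]))),
      paste0("expected_log_ratio_", names(config$purity))
    ))

  variants_and_truth <- plant_variants(model, coverage, cn, config)

  truth <- structure(list(
    segments = truth_segments,
    variants = variants_and_truth$truth,
    purities = config$purity
  ), class = "truth_set")

  structure(list(model = model, coverage = coverage,
                 variants = variants_and_truth$records, truth = truth),
            class = "sim_cohort")
}

plant_variants <- function(model, coverage, cn, config) {
  samples <- cov_samples(coverage)
  blood <- samples[1]
  tumors <- samples[-1]
  n <- nrow(model)
  counts <- as.matrix(as_tibble(coverage)[, samples])

  n_germ <- config$germline_het_count + config$rare_germline_count
  del_rows <- which(apply(cn, 1, function(z) any(z < 2)))
  neutral_rows <- which(apply(cn, 1, function(z) all(z == 2)))

  n_planted <- n_germ + config$somatic_neutral_count +
    config$somatic_in_cnv_count + config$noise_variant_count
  if (n_planted > n) abort("more planted variants than exons")

  pick <- function(pool, k, used) {
    avail <- setdiff(pool, used)
    if (length(avail) < k) abort("not enough exons to place variants")
    sample(avail, k)
  }
  used <- integer(0)
  germ_rows <- pick(seq_len(n), n_germ, used); used <- c(used, germ_rows)
  som_neutral <- pick(neutral_rows, config$somatic_neutral_count, used)
  used <- c(used, som_neutral)
  som_cnv <- pick(del_rows, min(config$somatic_in_cnv_count, length(del_rows)),
                  used)
  used <- c(used, som_cnv)
  noise_rows <- pick(seq_len(n), config$noise_variant_count, used)

  bases <- c("A", "C", "G", "T")
  mk_site <- function(rows) {
    ref <- sample(bases, length(rows), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    tibble(exon = rows, chrom = model$chrom[rows],
           pos = model$start[rows] + 1L +
             as.integer(floor(runif(length(rows)) *
                                (model$end[rows] - model$start[rows]))),
           ref = ref, alt = alt)
  }

  alt_kept <- config$loh_lost_allele == "ref"
  records <- list()
  truth <- list()

  emit <- function(site, sample_set, af_by_sample, qual, var_class,
                   functional, known, type) {
    depth <- counts[site$exon, sample_set, drop = FALSE]
    purrr::map(seq_along(sample_set), function(j) {
      sm <- sample_set[j]
      d <- depth[, j]
      tibble(chrom = site$chrom, pos = site$pos, ref = site$ref,
             alt = site$alt, sample = sm, depth = d,
             alt_reads = rbinom(nrow(site), d, af_by_sample[[sm]]),
             qual = qual, var_class = var_class,
             functional = functional, known = known)
    })
  }

  # germline heterozygotes: blood AF 0.5, purity/CN-adjusted in tumors
  if (nrow_site <- n_germ) {
    site <- mk_site(germ_rows)
    known_flag <- c(rep(TRUE, config$germline_het_count),
                    rep(FALSE, config$rare_germline_count))
    func_flag <- c(runif(config$germline_het_count) < 0.5,
                   rep(TRUE, config$rare_germline_count))
    af <- list()
    af[[blood]] <- rep(0.5, nrow_site)
    for (tm in tumors) {
      cn_t <- cn[germ_rows, tm]
      a <- vapply(cn_t, alt_copies, 0, germline = TRUE, on_kept = alt_kept)
      af[[tm]] <- expected_af(config$purity[[tm]], cn_t, a, alt_in_normal = 1)
    }
    qual <- runif(nrow_site, 80, 250)
    recs <- emit(site, samples, af, qual, "snv", func_flag, known_flag,
                 "germline")
    records <- c(records, recs)
    truth <- c(truth, list(tibble(
      key = paste(site$chrom, site$pos, site$ref, site$alt, sep = ":"),
      type = "germline",
      copy_neutral = apply(cn[germ_rows, , drop = FALSE] == 2, 1, all),
      !!!setNames(af[samples], paste0("expected_af_", samples)))))
  }

  plant_somatic <- function(rows, on_kept, label) {
    if (length(rows) == 0) return(invisible())
    site <- mk_site(rows)
    af <- list()
    af[[blood]] <- rep(0, length(rows))
    for (tm in tumors) {
      cn_t <- cn[rows, tm]
      a <- vapply(cn_t, alt_copies, 0, germline = FALSE, on_kept = on_kept)
      af[[tm]] <- expected_af(config$purity[[tm]], cn_t, a, alt_in_normal = 0)
    }
    qual <- runif(length(rows), 60, 220)
    recs <- emit(site, tumors, af, qual, "snv", TRUE, FALSE, label)
    records <<- c(records, recs)
    truth <<- c(truth, list(tibble(
      key = paste(site$chrom, site$pos, site$ref, site$alt, sep = ":"),
      type = label,
      copy_neutral = apply(cn[rows, , drop = FALSE] == 2, 1, all),
      !!!setNames(af[samples], paste0("expected_af_", samples)))))
  }
  plant_somatic(som_neutral, on_kept = TRUE, "somatic_neutral")
  plant_somatic(som_cnv, on_kept = TRUE, "somatic_in_cnv")

  # artifact calls: one random sample each, low quality and support
  if (config$noise_variant_count > 0) {
    site <- mk_site(noise_rows)
    sm <- sample(samples, config$noise_variant_count, replace = TRUE)
    d <- counts[cbind(site$exon, match(sm, samples))]
    cls <- sample(c("snv", "indel"), config$noise_variant_count,
                  replace = TRUE, prob = c(0.8, 0.2))
    records <- c(records, list(tibble(
      chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
      sample = sm, depth = d,
      alt_reads = pmin(d, rbinom(config$noise_variant_count, d,
                                 runif(config$noise_variant_count, 0.01, 0.15))),
      qual = runif(config$noise_variant_count, 0, 60),
      var_class = cls,
      functional = runif(config$noise_variant_count) < 0.3,
      known = runif(config$noise_variant_count) < 0.7)))
  }

  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), sample = character(), depth = integer(),
                  alt_reads = integer(), qual = numeric(),
                  var_class = character(), functional = logical(),
                  known = logical())
  recs <- variant_records(dplyr::bind_rows(c(list(empty), records)))
  recs <- dplyr::arrange(recs, match(.data$chrom, unique(model$chrom)),
                         .data$pos, .data$sample)
  list(records = recs, truth = dplyr::bind_rows(truth))
}

#' Simulate a CNV-free blood/tumor coverage pair
#'
#' Null cohort for calibrating the per-exon ratio test: blood and tumor
#' counts are drawn independently from identical per-exon rates (shared
#' capture effect, no copy-number change, purity irrelevant).
#'
#' @param n_exons Number of exons.
#' @param mean_depth Expected read count per exon (both samples).
#' @param seed Integer seed.
#' @param overdispersion Lognormal sd of the shared capture effect.
#' @param n_chrom Chromosomes to spread exons over.
#' @return A [coverage_matrix] with samples `blood` and `tumor`.
#' @export
make_null_cohort <- function(n_exons, mean_depth = 150, seed = 1,
                             overdispersion = 0.3, n_chrom = 10) {
  config <- simulation_config(
    n_exons = n_exons, n_chrom = n_chrom,
    mean_depth = c(blood = mean_depth, tumor = mean_depth),
    purity = c(tumor = 0),
    truth_segments = tibble(chrom = character(), start_exon = integer(),
                            end_exon = integer(), copy_number = integer()),
    germline_het_count = 0, rare_germline_count = 0,
    somatic_neutral_count = 0, somatic_in_cnv_count = 0,
    noise_variant_count = 0,
    overdispersion = overdispersion, seed = seed)
  simulate_cohort(config)$coverage
}
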