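# Shared builders for small in-code fixtures.

make_variant_table <- function(...) {
  rows <- list(...)
  defaults <- list(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                   sample = "OV", depth = 100L, alt_reads = 30L,
                   qual = 60, var_class = "snv", functional = TRUE,
                   known = FALSE)
  tab <- purrr::map_dfr(rows, function(r) {
    out <- utils::modifyList(defaults, r)
    tibble::as_tibble(out)
  })
  variant_records(tab)
}

random_variant_table <- function(n, seed) {
  set.seed(seed)
  samples <- c("blood", "OV", "OMN", "REC")
  depth <- rpois(n, 120) + 1L
  variant_records(tibble::tibble(
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "N",
    sample = sample(samples, n, replace = TRUE),
    depth = depth,
    alt_reads = rbinom(n, depth, runif(n, 0, 0.6)),
    qual = runif(n, 0, 120),
    var_class = sample(c("snv", "indel"), n, replace = TRUE),
    functional = runif(n) < 0.5,
    known = runif(n) < 0.5))
}

random_segment_table <- function(n, seed) {
  set.seed(seed)
  start <- as.integer(sort(sample.int(1e7, n)))
  mean_lr <- round(runif(n, -1, 1), 4)
  mean_lr[mean_lr == 0] <- 0.1
  segment_table(tibble::tibble(
    sample = sample(c("OV", "OMN"), n, replace = TRUE),
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    start = start, end = start + sample.int(1e5, n),
    n_exons = sample.int(500, n),
    mean_log_ratio = mean_lr,
    combined_p = runif(n, 1e-12, 1),
    call = ifelse(mean_lr < 0, "del", "amp")))
}

# Two-segment cohort used by recovery tests: one 300-exon single-copy
# deletion and one 300-exon single-copy gain in a 6000-exon exome.
recovery_config <- function(seed, purity = c(T1 = 0.85)) {
  simulation_config(
    n_exons = 6000, n_chrom = 6,
    mean_depth = c(blood = 174, setNames(rep(150, length(purity)),
                                         names(purity))),
    purity = purity,
    truth_segments = tibble::tibble(
      chrom = c("chr2", "chr5"),
      start_exon = c(351L, 351L), end_exon = c(650L, 650L),
      copy_number = c(1L, 3L)),
    germline_het_count = 0, rare_germline_count = 0,
    somatic_neutral_count = 0, somatic_in_cnv_count = 0,
    noise_variant_count = 0, seed = seed)
}

# Truth exon rows for a simulated cohort's segments, per chromosome.
truth_rows <- function(model, truth_segments) {
  purrr::pmap(truth_segments[, c("chrom", "start_exon", "end_exon")],
              function(chrom, start_exon, end_exon) {
                which(model$chrom == chrom)[start_exon:end_exon]
              })
}
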