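#' Validate a table of variant records
#'
#' A variant record is one called variant in one sample, carrying the
#' evidence the downstream filters need: read depth, alt-supporting reads,
#' Phred-scaled call quality, the variant class (`snv`/`indel`), a
#' functional flag (protein-coding or canonical splice site) and a known
#' flag (previously seen in population databases or control exomes).
#'
#' @param x A data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `sample`, `depth`, `alt_reads`, `qual`, `var_class`,
#'   `functional`, `known`.
#' @return The validated tibble (column-typed, same row order).
#' @export
variant_records <- function(x) {
  x <- as_tibble(x)
  need <- c("chrom", "pos", "ref", "alt", "sample", "depth", "alt_reads",
            "qual", "var_class", "functional", "known")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x[, need]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$ref <- as.character(x$ref)
  x$alt <- as.character(x$alt)
  x$sample <- as.character(x$sample)
  x$depth <- as.integer(x$depth)
  x$alt_reads <- as.integer(x$alt_reads)
  x$qual <- as.numeric(x$qual)
  x$var_class <- as.character(x$var_class)
  x$functional <- as.logical(x$functional)
  x$known <- as.logical(x$known)
  if (any(x$alt_reads > x$depth, na.rm = TRUE)) {
    i <- which(x$alt_reads > x$depth)[1]
    abort(sprintf("alt_reads > depth at %s:%d in sample %s",
                  x$chrom[i], x$pos[i], x$sample[i]))
  }
  if (any(x$alt_reads < 0 | x$depth < 0, na.rm = TRUE)) {
    abort("negative read counts in variant table")
  }
  if (any(x$qual < 0, na.rm = TRUE)) abort("negative qual in variant table")
  if (any(x$ref == x$alt)) abort("ref == alt in variant table")
  if (!all(x$var_class %in% c("snv", "indel"))) {
    abort("var_class must be 'snv' or 'indel'")
  }
  x
}

#' Variant key strings
#'
#' `chrom:pos:ref:alt` keys used for somatic subtraction and blacklists.
#'
#' @param x A variant table (or any data frame with `chrom`, `pos`, `ref`,
#'   `alt`).
#' @return Character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

infer_var_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv", "indel")
}

#' Read variant records from VCF or TSV
#'
#' Two on-disk dialects map to the same record table:
#' * **VCF v4.x** — per-sample `DP` and `AD` FORMAT fields supply depth and
#'   alt-supporting reads; site `QUAL` supplies the Phred score;
#'   `FUNCTIONAL` and `KNOWN` INFO flags supply the annotation booleans;
#'   variant class is inferred from allele lengths. Multi-allelic rows are
#'   split into one record per alternate allele, and samples whose `DP` is
#'   missing at a site contribute no record.
#' * **TSV** — a tab-delimited file carrying the record columns directly
#'   (see [variant_records]).
#'
#' @param path Path to a `.vcf` or `.tsv` file (format detected from the
#'   extension, falling back to content sniffing).
#' @return A validated variant tibble, one row per (sample, allele).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path) ||
    (!grepl("\\.tsv$", path) &&
       startsWith(readr::read_lines(path, n_max = 1), "##fileformat=VCF"))
  if (is_vcf) read_variant_vcf(path) else read_variant_tsv(path)
}

read_variant_tsv <- function(path) {
  variant_records(readr::read_tsv(path, show_col_types = FALSE,
                                  progress = FALSE, comment = "#"))
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0) abort("VCF has no sample columns")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  info <- fix[, "INFO"]
  has_flag <- function(flag) {
    grepl(paste0("(^|;)", flag, "(;|=|$)"), info)
  }
  functional <- has_flag("FUNCTIONAL")
  known <- has_flag("KNOWN")
  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    purrr::map(seq_along(samples), function(j) {
      if (is.na(dp[i, j])) return(NULL)
      ad_ij <- suppressWarnings(as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1]]))
      # AD is ref followed by one entry per alt allele
      alt_counts <- ad_ij[seq_along(alts) + 1]
      tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts, sample = samples[j],
        depth = as.integer(dp[i, j]), alt_reads = alt_counts,
        qual = as.numeric(fix[i, "QUAL"]),
        var_class = infer_var_class(fix[i, "REF"], alts),
        functional = functional[i], known = known[i]
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) abort(paste0("no usable variant records in ", path))
  variant_records(out)
}

#' Write variant records to TSV
#'
#' @param variants A variant table (see [variant_records]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variant_records(variants), path)
  invisible(path)
}

#' Read a blacklist of known-variant keys
#'
#' One `chrom:pos:ref:alt` key per line (or a TSV whose first column holds
#' the keys). Stands in for dbSNP/1000 Genomes/control-exome membership.
#'
#' @param path Path to the blacklist file.
#' @return Character vector of keys.
#' @export
read_blacklist <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
}
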