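#' Quality criteria for variant filtering
#'
#' Thresholds are inclusive ("no less than"): a call passes when its
#' Phred-scaled quality is at least 20 (SNV) or 50 (indel) and its read
#' depth at least 3. In addition, for the samples named in
#' `alt_support_samples` (by default the primary tumor), at least
#' `min_alt_reads` reads and at least `min_alt_fraction` of covering reads
#' must support the alternate base.
#'
#' @param min_qual_snv,min_qual_indel Minimum Phred-scaled quality.
#' @param min_depth Minimum total read depth.
#' @param min_alt_reads,min_alt_fraction Alt-support rule thresholds.
#' @param alt_support_samples Samples the alt-support rule applies to.
#' @return A list of class `quality_criteria`.
#' @export
quality_criteria <- function(min_qual_snv = 20, min_qual_indel = 50,
                             min_depth = 3, min_alt_reads = 3,
                             min_alt_fraction = 0.10,
                             alt_support_samples = "OV") {
  vals <- c(min_qual_snv, min_qual_indel, min_depth, min_alt_reads,
            min_alt_fraction)
  if (any(vals < 0)) abort("quality thresholds must be nonnegative")
  if (min_alt_fraction > 1) abort("min_alt_fraction must lie in [0, 1]")
  structure(list(min_qual_snv = min_qual_snv,
                 min_qual_indel = min_qual_indel,
                 min_depth = min_depth, min_alt_reads = min_alt_reads,
                 min_alt_fraction = min_alt_fraction,
                 alt_support_samples = alt_support_samples),
            class = "quality_criteria")
}

#' Apply quality filters to variant records
#'
#' Keeps records whose quality meets the class-specific Phred threshold and
#' whose depth meets `min_depth`; records from samples named in
#' `criteria$alt_support_samples` must additionally satisfy the
#' alt-support rule. Row order is preserved; the filter is idempotent.
#'
#' @param variants A variant table (see [variant_records]).
#' @param criteria A [quality_criteria].
#' @param check_samples Error when `alt_support_samples` names a sample not
#'   present in `variants` (default TRUE; set FALSE for already-subsetted
#'   tables).
#' @return The filtered tibble.
#' @export
apply_quality_filters <- function(variants, criteria = quality_criteria(),
                                  check_samples = TRUE) {
  variants <- variant_records(variants)
  unknown <- setdiff(criteria$alt_support_samples, unique(variants$sample))
  if (check_samples && length(unknown) > 0 && nrow(variants) > 0) {
    abort(paste0("alt_support_samples not present in variant table: ",
                 paste(unknown, collapse = ", ")))
  }
  min_qual <- ifelse(variants$var_class == "indel",
                     criteria$min_qual_indel, criteria$min_qual_snv)
  keep <- variants$qual >= min_qual & variants$depth >= criteria$min_depth
  needs_alt <- variants$sample %in% criteria$alt_support_samples
  alt_ok <- variants$alt_reads >= criteria$min_alt_reads &
    variants$alt_reads >= criteria$min_alt_fraction * variants$depth
  keep <- keep & (!needs_alt | alt_ok)
  variants[keep, , drop = FALSE]
}

#' Keep functional, previously unobserved variants
#'
#' Retains records located in protein-coding regions or canonical splice
#' sites (`functional == TRUE`) that have not been seen before
#' (`known == FALSE`). When a blacklist of `chrom:pos:ref:alt` keys is
#' supplied, membership overrides the `known` column.
#'
#' @param variants A variant table.
#' @param blacklist Optional character vector of known-variant keys (see
#'   [read_blacklist]).
#' @return The filtered tibble.
#' @export
filter_functional_rare <- function(variants, blacklist = NULL) {
  variants <- variant_records(variants)
  known <- variants$known
  if (!is.null(blacklist)) {
    known <- variant_key(variants) %in% blacklist
  }
  variants[variants$functional & !known, , drop = FALSE]
}

#' Call somatic variants by blood subtraction
#'
#' Removes every tumor record whose `chrom:pos:ref:alt` key carries alt
#' evidence in the matched blood sample. By default any blood record with
#' at least one supporting read excludes the key, regardless of blood-side
#' quality — cross-sample artifacts typically show low-level support in the
#' other samples, so aggressive subtraction is the safer default.
#'
#' @param tumor_variants Variant table of tumor records (one or several
#'   samples).
#' @param blood_variants Variant table of blood records.
#' @param min_blood_reads Minimum blood alt reads for a key to be
#'   subtracted (default 1 = any evidence).
#' @return The somatic tibble (all tumor samples; split by `sample` for
#'   per-sample lists, `unique(variant_key(result))` for the cross-tumor
#'   union).
#' @export
call_somatic <- function(tumor_variants, blood_variants,
                         min_blood_reads = 1) {
  tumor_variants <- variant_records(tumor_variants)
  blood_variants <- variant_records(blood_variants)
  blood_keys <- variant_key(
    blood_variants[blood_variants$alt_reads >= min_blood_reads, ,
                   drop = FALSE])
  tumor_variants[!variant_key(tumor_variants) %in% blood_keys, ,
                 drop = FALSE]
}
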