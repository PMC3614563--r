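Package: trioexome
Title: Matched Tumor-Normal Exome Analysis of Somatic Variants and Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of matched blood and multi-tumor exome cohorts (primary
    tumor, metastasis, recurrence): somatic variant filtering by quality
    criteria and blood subtraction, mutant allele-frequency trajectories
    across ordered samples with Sanger peak-height conversion and Spearman
    concordance, tumor purity estimation from clonal variant allele
    frequencies, and read-depth copy-number detection from per-exon RPKM
    log-ratios using a Geary-Hinkley ratio statistic,
    circular-binary-segmentation-style changepoint detection, segment
    smoothing and merging, and Fisher's-method segment p-values. Includes a
    synthetic-cohort generator with known copy-number, purity and
    allele-frequency truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
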