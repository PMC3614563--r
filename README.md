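# trioexome

Matched tumor–normal exome analysis for small cohorts sampled from one
patient: a blood (germline) exome plus several tumors taken along the
disease course — typically a primary tumor (OV), a metastasis (OMN) and a
post-therapy recurrence (REC). The package is aimed at cancer-genomics
analysts who have per-sample variant calls and per-exon read counts in
hand (alignment and raw calling already done) and want the downstream
science: which variants are somatic, how their mutant allele frequencies
move across tumors, how pure each tumor sample is, and which large
chromosomal deletions and amplifications the read-depth signal supports.

## What it computes

**Somatic variant filtering.** Raw calls are filtered by inclusive
quality criteria — Phred quality ≥ 20 for SNVs and ≥ 50 for indels, depth
≥ 3, and (for the primary tumor) ≥ 3 alt reads supporting ≥ 10% of
coverage — then restricted to functional (coding/splice) variants absent
from population databases and control exomes, and finally reduced to
somatic calls by subtracting every variant with any evidence in the
matched blood.

**Allele-frequency dynamics.** Exome allele frequency is alt reads over
depth; Sanger chromatogram measurements convert from the peak-height
allele proportion r = alt/ref to frequency r/(1+r). Trajectories across
ordered samples select "rising" variants (later AF at least 10% above the
primary-tumor AF), and exome/Sanger agreement is scored as a pooled
Spearman rank correlation. Because a clonal somatic variant in a
copy-neutral region has expected AF π/2 at tumor purity π, purity is
estimated as twice the median such AF — rising AFs across tumors are then
read as increasing purity rather than clonal selection.

**Read-depth copy-number calling.** Per-exon counts are normalized to
RPKM (reads per kilobase of exon model per million mapped reads) and the
per-exon statistic is the Geary–Hinkley transformation of the tumor/blood
ratio R = n_t/(s·n_b) (s the library-size ratio):

    t = sqrt(n_b) · (R − 1) / sqrt(R² + 1/s),   p = 2·(1 − Φ(|t|))

standard normal under no copy-number change. Log₂ RPKM ratios are
segmented by a circular-binary-segmentation-style permutation splitter,
segments are smoothed (adjacent same-sign segments merged, calls with
< 100 exons or |mean log-ratio| < 0.1 dropped — the large-event focus),
and each surviving segment gets a Fisher's-method combined p-value
(−2Σln pᵢ ~ χ² with 2k df). A segment at copy number c and purity π sits
at log₂(((1−π)·2 + π·c)/2), so deletions in an impure primary (~ −0.1 to
−0.4) sharpen toward −0.5 and beyond in purer tumors.

**Synthetic cohorts.** `simulate_cohort()` generates matched cohorts with
known truth — shared lognormal capture effects × Poisson counts, planted
CNV segments, germline heterozygotes with LOH, clonal somatic variants
with purity-determined AFs — so every stage has a parameter-recovery test
with no external data.

## Worked example

```r
library(trioexome)

# packaged fixture: 24 Sanger-validated somatic mutations in a matched
# ovarian carcinoma trio, AFs from exome and Sanger sequencing
ser <- validated_trio_af()
concordance(ser)
#> Exome vs Sanger AF concordance: Spearman rho = 0.783 (p = 8.37e-15, n = 66 pairs)

rising <- select_rising_variants(ser, baseline = "OV", later = c("OMN", "REC"))
length(unique(rising$key))
#> [1] 24

# synthetic matched cohort: blood 174x, tumors 130/162/146x, purities
# 0.4 / 0.85 / 0.9, one 400-exon deletion (chr17) and amplification (chr8)
co <- simulate_cohort(simulation_config(n_exons = 20000, seed = 1))
calls <- call_cnvs(co$coverage, "blood", "OMN", segmentation_params(seed = 1))
tidy(calls)
#> # A tibble: 2 × 8
#>   sample chrom  start    end n_exons mean_log_ratio combined_p call
#> 1 OMN    chr8  249000 647200     399          0.515     1e-300 amp
#> 2 OMN    chr17 249000 648200     400         -0.801     1e-300 del
```

The deletion mean of −0.801 matches the mixing-model expectation
log₂((0.15·2 + 0.85·1)/2) = −0.80 at purity 0.85; the floor of 1e-300 on
the combined p-value marks Fisher underflow over 400 exons. Purity comes
back from the planted copy-neutral somatic variants:

```r
som <- co$truth$variants$key[co$truth$variants$type == "somatic_neutral"]
v <- co$variants[variant_key(co$variants) %in% som & co$variants$sample != "blood", ]
estimate_purity(build_frequency_series(v, c("OV", "OMN", "REC")))
#> # A tibble: 3 × 4
#>   sample pi_hat n_variants method
#> 1 OV      0.394         20 2 x median AF, copy-neutral clonal
#> 2 OMN     0.862         20 2 x median AF, copy-neutral clonal
#> 3 REC     0.909         20 2 x median AF, copy-neutral clonal
```

`run_pipeline(pipeline_config(...))` chains every stage (simulation or
file inputs → filters → somatic → trajectories → purity → CNV) into one
seeded, reproducible run; `inst/cli/trioexome.R` exposes the same stages
as `simulate`/`filter`/`somatic`/`track`/`cnv`/`run` subcommands for
shell use. Plots: `autoplot()` on CNV calls and concordance results,
`plot_af_trajectories()` on frequency series.

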