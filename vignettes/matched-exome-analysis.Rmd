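---
title: "Methods: somatic filtering, allele-frequency dynamics and read-depth CNV calling in matched tumor exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched tumor exome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioexome)
```

# The study design

The package analyzes a matched cohort sampled from a single patient: one
blood exome giving the germline, and several tumor exomes taken along the
disease course — here labeled OV (primary), OMN (omental metastasis) and
REC (post-therapy recurrence). Two signals are extracted from the same
sequencing data:

* the **variant channel**: which calls are somatic, and how the mutant
  allele frequency (AF) of each somatic variant moves across the ordered
  tumor samples;
* the **depth channel**: which large chromosomal segments are deleted or
  amplified, read off the tumor-versus-blood coverage ratio per exon.

Both channels are modulated by **tumor purity** π, the fraction of
malignant cells in the biopsy. A clonal somatic variant in a diploid
region has expected AF π/2; a heterozygous germline variant whose wild-type
allele is lost (LOH) rises to 1/(2−π); and a segment at integer copy
number c sits at an expected log₂ depth ratio of

$$\log_2\frac{(1-\pi)\cdot 2 + \pi c}{2}.$$

This shared dependence is the scientific crux: when AFs and CNV
log-ratios all move together from one tumor to the next, the parsimonious
reading is a change of purity, not parallel selection on every locus. The
package makes that reading quantitative by estimating π per sample and by
comparing recovered log-ratios against the mixing model.

# Variant filtering

`apply_quality_filters()` implements inclusive thresholds ("no less
than"): Phred-scaled quality ≥ 20 for SNVs and ≥ 50 for indels, total
depth ≥ 3 reads. The alt-support rule — at least 3 reads and at least 10%
of covering reads supporting the alternate base — applies by default only
to the primary tumor, where low purity makes marginal support common; it
is configurable to any sample set. The depth criterion counts total
depth, not alt reads, for samples outside the alt-support set; this is
the literal reading of "read coverage" and the one we implement.

`filter_functional_rare()` keeps variants that are functional (protein
coding or canonical splice site) and previously unobserved. "Known"
status is an input column, optionally overridden by a local blacklist of
`chrom:pos:ref:alt` keys standing in for dbSNP, 1000 Genomes and
control-exome sets; there are no live database queries, so results are
reproducible against a frozen blacklist.

`call_somatic()` subtracts from the tumor lists every key with **any**
alt evidence in blood, regardless of blood-side quality. The aggressive
default is deliberate: cross-tumor "unique" calls in this design are
typically alignment artifacts that show low-level support in the other
samples, so requiring blood evidence to pass its own quality bar would
leak germline variation into the somatic list. A `min_blood_reads`
override relaxes this for very deep blood libraries.

These three operations are set filters on the record table, so they are
idempotent and mutually commuting — both properties are tested on
randomized tables, and the somatic list on a cohort with no planted
somatic variants is verified to be empty.

# Allele-frequency dynamics

Exome AF is `alt_reads / depth` (missing, not an error, at zero depth).
Sanger chromatograms measure the **allele proportion** r = alt peak
height / ref peak height; `proportion_to_frequency()` maps it to an AF by
r/(1+r), with the limits pinned explicitly (no alt peak → 0, no ref peak
→ 1). The map is strictly increasing from (0, ∞) onto (0, 1) and its
inverse f/(1−f) round-trips to 1e−12 on a dense grid.

`select_rising_variants()` keeps variants whose best later-sample AF
exceeds the primary-tumor AF by at least 10%. The threshold is
**relative** by default (`af_later ≥ 1.1 · af_primary`): an absolute
reading (+0.10) would exclude genuinely validated risers with shallow
slopes such as a 0.17 → 0.21 trajectory, and the relative reading is the
one consistent with the validated sets this style of analysis reports.
Absolute mode is available for stricter selection.

`concordance()` pools one (exome AF, Sanger AF) pair per variant per
tumor sample — the pooled-scatter convention — drops pairs with a missing
member, and computes Spearman's rank correlation with average ranks for
ties (AF tables routinely contain duplicated values). The p-value uses
the t approximation on n−2 degrees of freedom. Which rows enter the pool
is the one genuinely ambiguous choice: we pool all variants with Sanger
measurements across all three tumors (66 pairs on the packaged fixture,
including its outlier pair and the measured indel) and report `n_pairs`
alongside rho; a per-sample stratified breakdown is also returned.

`estimate_purity()` inverts AF = π/2 as π̂ = 2 · median(AF) over clonal
somatic variants in copy-number-neutral regions, clipped to [0, 1]. The
median resists the occasional subclonal or mis-annotated variant; the
estimator assumes one clone per tumor, which is the regime this design
addresses (no new mutations appear between tumors). Copy-neutral status
comes from the CNV calls (pipeline) or from simulation truth (tests).

# Read-depth CNV calling

Coverage is normalized per exon to RPKM — count / (exon kb) / (library
millions) — so tumor and blood are comparable despite different library
sizes. The per-exon test works on counts: with library ratio
s = total_tumor/total_blood, both sides are placed on the blood scale and
treated as approximately normal with Poisson variance. The Geary–Hinkley
transformation of the ratio R = n_t/(s·n_b),

$$t = \frac{\sqrt{n_b}\,(R - 1)}{\sqrt{R^2 + 1/s}},$$

is approximately standard normal under no copy-number change, giving the
per-exon two-sided p-value 2(1−Φ(|t|)). Two numerical conventions are
worth recording. First, the transformation is anchored so that R = 1
gives exactly t = 0. Second, the two-sided form is used as written; a
case split of the tail formula at t = 1 (rather than 0) appears in some
descriptions of this statistic, but it is discontinuous and not a
probability near t = 1, so we treat it as typographical and use the
standard form — the property that matters, null calibration, is tested
directly (the empirical fraction of p < 0.05 on a 10⁴-exon null cohort
must land in [0.040, 0.061]).

Exons whose **blood** count falls below 10 are masked, not zero-filled:
the ratio statistic is unstable at small denominators, and a masked exon
carries no t, p or log-ratio. Segmentation runs on the unmasked,
finite log₂ RPKM ratios per chromosome.

The segmenter is written from scratch in the package (C++ core), in the
circular-binary-segmentation style: each step scans all boundary pairs
(i, j] for the maximal two-sample mean-shift statistic between the arc
and its complement, accepts the split if a seeded permutation test
(default 1000 permutations) gives p < α = 0.01, and recurses into the
three resulting pieces. The permutation loop short-circuits in both
directions — a permutation scan stops as soon as it exceeds the observed
maximum, and the whole loop stops once enough exceedances accumulate that
p cannot fall below α — which makes flat chromosomes cheap. We
deliberately implement rather than wrap an existing segmentation package:
equivalence to any particular implementation is not claimed; recovery of
planted truth is the test.

`smooth_and_merge()` then applies the large-event focus: adjacent
same-sign segments whose means differ by ≤ 0.2 are merged with
exon-count weighting (large CNVs are often reported as several segments
when exonic data gaps interrupt them), and segments with fewer than 100
exons or |mean log-ratio| < 0.1 are dropped. The 100-exon rule is
implemented as a filter (the conservative reading of "identified regions
contain at least 100 exons"); min_exons, the merge tolerance and the call
threshold are all configuration. The defaults keep primary-tumor-level
attenuated signals (|mean| ≈ 0.13–0.4 at π ≈ 0.4) callable while
suppressing focal noise. Surviving segments get a Fisher's-method
combined p-value, −2Σln pᵢ against χ²(2k); underflow is floored at
1e-300 rather than reported as 0.

# What the simulator emulates — and what it does not

`simulate_cohort()` draws per-exon counts as Poisson(mean_depth · g ·
dosage), where g is a lognormal capture-efficiency multiplier (sd 0.3 on
the log scale) **shared across samples** and dosage = ((1−π)·2 + πc)/2.
The shared g is the reason matched designs work: capture bias cancels in
the tumor/blood ratio, exactly as in real exomes; the overdispersion knob
exists to stress the normality assumption of the ratio test. Library
totals are the on-target sums plus an off-target component computed from
the diploid expectation — off-target reads are genome-wide and
essentially insensitive to a focal CNV, so a deleted segment must not
drag the normalizer with it. For the same reason, cohorts used to check
the attenuation law place the 10⁴-exon deletion inside a 2×10⁵-exon
exome, the scale of a real whole-exome capture design: if the CNV were a
large fraction of the design, part of its signal would be absorbed by
normalization (as it would in a real sample with that much genome
deleted).

Defaults mirror the study conditions: blood at 174× and tumors at
130×/162×/146×; purities 0.4/0.85/0.9 for OV/OMN/REC. The purities are
not measured facts — no quantitative estimates exist for this design —
but the configuration that reproduces the observed ordering of deletion
log-ratios (≈ −0.3 in the impure primary vs ≈ −0.53 in the purer tumors)
and the rising-AF pattern; they are config, not truth claims. Variants
are planted in three strata: germline heterozygotes (blood AF 0.5; LOH
inside deletions, by default losing the reference allele so the mutant AF
rises, the trajectory characteristic of an inherited predisposition
allele under LOH), clonal somatic variants with purity/copy-number
determined AFs, and low-quality single-sample artifacts for the filters
to remove. Alt counts are Binomial(depth, expected AF).

Not modeled: read-level errors and mapping bias (inputs are counts, not
reads), subclonal structure (one clone per tumor, matching the no-new-
mutations regime this design targets), GC-dependent bias beyond the
shared lognormal effect, and allele-specific copy number. Passing
recovery tests therefore demonstrates correctness of the statistical
chain under a faithful abstraction of matched-exome noise — not
robustness to alignment artifacts or clonal heterogeneity in real data.

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to make
sampling error small relative to the tolerances they check: 10⁴-exon null
cohorts for calibration (binomial s.e. ≈ 0.002 on the 5% rate), a
10⁴-exon deletion for the attenuation law (s.e. of the mean log-ratio
≈ 0.002), ten seeded 6000-exon cohorts with one planted 300-exon deletion
and amplification each for segment recovery, and 20 somatic variants at
depth 150 per purity level for purity recovery. Every stochastic stage is
seeded; `run_pipeline()` fans a single global seed into per-stage child
seeds so stages can be re-run standalone with identical results, and
records a config hash in its report.

# Known limitations

* Segment boundaries are exon-resolution; breakpoints inside intronic
  gaps are attributed to the flanking exons.
* The Geary–Hinkley normal approximation degrades at low counts; the
  blood-count mask (default 10) bounds the damage but exons just above
  the mask are the least calibrated.
* Fisher's method assumes independent exon p-values; residual shared
  noise within a segment makes combined p-values anti-conservative,
  which is why calling is driven by the mean log-ratio and exon-count
  thresholds, with the combined p reported as a summary rather than used
  as the gate.
* `estimate_purity()` is a clonal-diploid estimator: amplifications
  containing the variant, copy-neutral LOH, or subclonality bias it.
* The blood-subtraction default can discard true somatic variants when
  the blood sample carries low-level tumor contamination.
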