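---
title: "Dosage effect scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage effect scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(descna)
```

## The model

`descna` asks, gene by gene, whether copy-number alterations (CNAs) in a
tumor cohort produce concordant changes in that gene's own expression — a
*cis* dosage effect. The score is deliberately non-parametric: it makes no
assumption about the shape of the CN–expression relationship, only that a
dosage-driven expression change should stand out against the spread of the
copy-neutral samples.

For a gene with linear-scale copy numbers (diploid = 2) across `n`
samples:

1. samples are trichotomized into loss (CN < 1.7), copy-neutral
   (1.7 ≤ CN ≤ 2.3) and gain (CN > 2.3);
2. the copy-neutral samples define the gene's reference expression mean μ
   and standard deviation σ (sample SD, n − 1 denominator);
3. a gain sample is concordant when its expression is strictly above
   μ + kσ, a loss sample when strictly below μ − kσ (k = 1 by default);
4. DES = concordant count / CNA count.

The neutral band [1.7, 2.3] is inclusive at both ends; the CNA calls use
strict inequalities. The asymmetric-looking band is symmetric around 2 and
its width reflects two facts about SNP-array copy numbers of bulk tumors:
measurement noise, and dilution by normal cells, which pulls a true
single-copy change of ±1 toward 2 by roughly the non-tumor fraction. The
same attenuation is why a cohort's trisomic chromosomes peak near 2.6
rather than 3 at typical purity (~0.6), and why the hyperdiploidy cutoff
sits at 2.3, midway between the diploid peak at 2.0 and the attenuated
trisomy peak at 2.6.

## Guards: when DES is not reported

A ratio of small counts is noise. `compute_des()` therefore leaves DES
undefined (with a recorded reason) when:

- the CNA count is not greater than 10 % of the cohort
  (`min_cna_fraction = 0.10`, strict);
- fewer than 5 copy-neutral samples exist (`min_neutral_samples = 5`) —
  a mean and SD from fewer points is too unstable to define the
  concordance band; or
- the neutral SD is exactly zero, which makes the band degenerate.

The first guard is part of the score's definition; the latter two are this
package's choices for numerical sanity. In practice the 10 % guard is the
binding one: genes on quiet chromosomes have almost no CNA samples, so most
of the genome is reported as "undefined — low CNA frequency" rather than
given a spurious score.

## Categories and derived summaries

Defined scores are banded as low (DES < 0.2), medium (0.2 ≤ DES ≤ 0.4,
inclusive at both bounds) and high (DES > 0.4); high-DES genes are the
dosage-sensitive set. Dosage-resistant genes are the complementary
phenomenon: genes in the top 20 % by median expression whose DES is
defined and below 0.2 — strongly expressed, yet buffered against copy
number.

Two cohort-level summaries are built on the categories. The
expression-strata trend (`expression_group_trend()`) ranks defined-DES
genes by median expression, splits them into five equal groups (remainder
to the lower groups; boundary ties broken by gene symbol so the split is
deterministic) and tests the proportion of high-DES genes for a monotone
trend with the Cochran–Armitage statistic. The chromosome summary
(`chromosome_summary()`) gives per-chromosome category proportions and the
mean per-gene CNA fraction, the numbers behind the karyotype figure.

## Statistical components

- **Cochran–Armitage trend.** Asymptotic z with the variance conditional
  on all margins (including the finite-population factor N/(N−1)); for
  totals ≤ 30 the p-value is computed exactly by enumerating all tables
  with the observed margins under the multivariate hypergeometric
  distribution, two-sided by |T|. A table in which every gene (or none) is
  high-DES carries no gradient; `expression_group_trend()` reports z = 0,
  p = 1 for it rather than erroring, while the bare test rejects
  zero-margin input.
- **Fisher exact test / overlap significance.** Two-sided by the
  probability-mass criterion; the reported odds ratio is the sample
  cross-product ratio with a Haldane 0.5 correction when a cell is zero.
- **Two-proportion comparison.** Chi-square test of homogeneity without
  continuity correction (equivalently, the two-sided pooled z-test).
- **Moderated differential expression.** Per-gene pooled-variance t with
  the variance shrunk halfway toward the across-gene median variance and
  the reference df inflated to 2(n₁ + n₂ − 2). This is a fixed-weight
  analogue of empirical-Bayes variance moderation: it stabilizes
  small-variance genes without fitting a prior. It does not reproduce any
  specific moderated-t implementation and is not meant to; under the null
  its p-values are calibrated (checked by simulation in the test suite),
  which is the property the downstream Fisher enrichment needs.
- **Multiplicity.** Benjamini–Hochberg step-up everywhere a family of
  tests is reported; significance is called at adjusted p < 0.05.

P-values below 2.2e-16 are displayed with the conventional "< 2.2e-16"
floor but stored unclipped.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage can be exercised,
end to end, against known truth without external data. It emulates the
CNA architecture of a myeloma-like cohort:

- two subtypes: hyperdiploid samples (probability 0.5) carry true copy
  number 3 on all genes of chromosomes 3, 5, 7, 9, 11, 15, 19, 21;
- recurrent events with subtype-specific probabilities: chromosome 13 loss
  (0.1 in HMM, 0.7 in NHMM), 1q gain (0.3 / 0.5), 8p loss (0.2 / 0.2),
  16q loss (0.2 / 0.2) — whole chromosomes or arms, not focal events;
- per-sample purity ~ Normal(0.6, 0.1), clamped to [0.05, 1]: observed
  CN = 2 + purity·(trueCN − 2) + Normal(0, 0.08), floored at 0.1, which
  reproduces the observed bimodality of median trisomy CN at 2.0 / 2.6;
- genes allocated to the 22 autosomes proportionally to plausible
  chromosome lengths, evenly spaced, 20 kb transcripts;
- 30 % of genes are dosage sensitive (s_g = 1): log2 expression =
  μ_g + s_g·log2(CN_att / 2) + Normal(0, 0.5), with μ_g ~ Normal(8, 2)
  and CN_att the purity-attenuated copy number, so expression tracks the
  dosage actually visible in the CN data.

All draws come from one seeded stream in a fixed order (subtype, purity,
event indicators, sensitivity, baseline expression, CN noise, expression
noise), so a seed pins the cohort bit-for-bit.

What the generator does *not* model: focal/sub-arm events, translocations,
subclonal mixtures, copy-neutral LOH, probe-level artifacts,
normalization-induced correlation between genes, and any dependence of
sensitivity on expression level (sensitivity and μ_g are drawn
independently — which is exactly what makes the generator a valid null for
the expression-strata trend test). Tests passing on this generator
demonstrate the pipeline's internal correctness and statistical
calibration, not biological fidelity on real arrays.

## Numerical and design choices

- **Gene-level copy number** is the mean over SNPs within 5 kb of the
  transcription region, window inclusive at both ends, strand ignored; a
  SNP inside two overlapping windows contributes to both genes. Genes with
  no SNP in the window get an explicit missing value (never an imputed 2)
  and are excluded from scoring with a logged count.
- **Probe collapsing** uses the arithmetic mean of a gene's probes.
- **Ploidy medians** are taken over gene-level copy numbers, keeping a
  single data path from preprocessing onward; HMM requires the median to
  exceed the cutoff strictly, consistent with the gain threshold being
  exclusive, so a sample sitting exactly at 2.3 is non-hyperdiploid.
- **Automatic cutoff estimation** (`estimate_cutoff()`) replaces eyeballing
  the histogram: Gaussian KDE with Silverman's bandwidth, local maxima at
  least 0.2 CN apart, midpoint of the two highest; unimodal densities fall
  back to 2.3 with a warning, and fewer than 20 samples is an error
  because a KDE mode estimate on less is folklore.
- **Coordinates** are 1-based inclusive throughout; `chr13` and `13`
  chromosome dialects are both accepted and normalized to bare labels.
- **Linear copy numbers are enforced**: a matrix whose overall median is
  below 1 is rejected with a hint that log-ratio input was supplied, since
  every threshold in the method lives on the linear scale.
- **Worked-example discrepancy.** The motivating worked example reports a
  concordant fraction written both as 25.29 % and as .2559 alongside a CNA
  fraction of 55.88 % and a score of 0.45; only 0.2529/0.5588 rounds to
  0.45 (0.2559/0.5588 gives 0.458 → 0.46), so the percentage form is
  treated as authoritative here.
- **Category denominators.** Published category proportions can be read
  against all genes or against defined-DES genes; the package reports
  percentages among defined-DES genes in the histogram annotation and
  exposes the counts so either denominator can be formed.

## Problem sizes used in validation

The test suite runs entirely on simulated data at sizes chosen to make
each statistical property measurable: the default 200 × 2000 cohort for
truth recovery (AUROC of DES against planted labels) and bimodality of the
ploidy medians; 60 × 300 cohorts, 200 replicates, for the uniformity of
the trend p-value when sensitivity is independent of expression; 2000
genes × 60 samples for differential-expression null calibration;
exhaustive enumeration for the exact oracles (all 2×2 tables with total
≤ 40, trend tables with total ≤ 30, brute-force DES on cohorts ≤ 12
samples).

## Limitations

The score is *cis*-only: it cannot see trans effects of an amplified
regulator, and it treats each gene independently. It is undefined — by
construction — wherever CNAs are rare, so it says nothing about dosage
sensitivity of genes in quiet regions. The concordance criterion is
binary (beyond 1 SD or not); genes with strong but sub-threshold shifts
score low. The neutral band is global, so cohorts with very low purity
will misclassify true single-copy events as neutral and deflate scores;
re-estimate the band or the purity upstream in that case. Finally, the
moderated t is a pragmatic calibrated test, not a full empirical-Bayes
treatment; for publication-grade differential expression on real arrays a
dedicated package is the right tool, and the pipeline's DE stage exists to
rank and count, not to be the contribution.
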