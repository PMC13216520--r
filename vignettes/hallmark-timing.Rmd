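---
title: "Timing genome instability from hallmark VAF profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing genome instability from hallmark VAF profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallmarktiming)
```

## The model and its assumptions

A somatic mutation's variant allele frequency is used here as an ordinal
proxy for its age: clonal mutations, present in every tumor cell, sit at
higher VAF than subclonal ones. Averaging VAF over the mutations that hit
genes of each of the ten canonical cancer hallmarks gives, per patient, a
ten-dimensional profile whose descending order approximates the order in
which the hallmarks were functionally altered. The central dichotomy is
whether the genome-instability hallmark ranks early (EGI tumors) or late
(LGI tumors).

This proxy carries real assumptions, all inherited by every downstream
statistic:

* VAF is treated as purity- and copy-number-naive. Amplified regions inflate
  VAF, low-purity samples deflate it; neither is corrected. CCF-based timing
  is explicitly out of scope.
* A mutation in a gene mapped to several hallmarks contributes to each of
  them; hallmark means are therefore not independent across hallmarks.
* The gene-to-hallmark map is an explicit user input. No map ships with the
  package, because no canonical public assignment exists; the synthetic
  generator emits its own map alongside each cohort.

## The pipeline, stage by stage

**Profiles and ranks.** `compute_hallmark_profiles()` averages VAF per
patient and hallmark. Patients missing more than `max_missing = 2` of the
ten hallmarks are excluded rather than imputed — a profile dominated by
imputed values carries no ordering signal; the remaining gaps are filled,
when `impute = TRUE`, with the patient's overall mean VAF, which is
rank-neutral. Ranks are descending with averaged ties.

**Clustering.** PCA is mean-centred but not variance-scaled: all ten
coordinates are VAFs on the same scale, so scaling would only amplify noisy
hallmarks (a `scale.` switch exists). All components are retained, so
k-means on the scores is exactly k-means on the centred data (Euclidean
k-means is rotation-invariant; a test verifies this). The cluster number is
chosen where the WSS decrease diminishes most sharply — the k maximizing the
second forward difference of the WSS curve, ties to the smallest k. A
linearly decaying curve has no curvature anywhere; the smallest interior k
is then returned with a `no_clear_elbow` flag rather than pretending a
choice was made. k-means runs `n_init = 25` restarts, 300 iterations,
seed-deterministic; silhouette widths (Euclidean, singletons scored 0)
summarize cluster quality. The cluster whose patients give the
genome-instability hallmark the lower mean rank is labelled EGI; the margin
between the two cluster means is reported as a confidence diagnostic, and an
exact tie (below 1e-9) is an error rather than an arbitrary call.

**SBS96 classification and refitting.** Substitutions are keyed by the
pyrimidine-strand substitution class and both flanking bases: purine
references are reverse-complemented together with their context, giving the
6 x 16 = 96 channels in COSMIC order (C>A block first, alphabetical flanks).
Indels, complex variants, and records whose context disagrees with the
reference base are rejected and counted per reason. Samples with fewer than
50 classified mutations are excluded before refitting — below that, weight
estimates are dominated by sampling noise. Refitting is a greedy forward
search: starting from zero weights, the single signature whose
golden-section-optimized weight most reduces the sum of squared errors
against the observed channel fractions is updated, until the best
improvement falls below `tol = 1e-3`. Raw weights are then normalized to
fractions of the observed spectrum, weights below `trim = 0.06` are zeroed,
and `1 - sum(weights)` (floored at 0) is reported as unexplained mass.
Normalize-then-trim (rather than refitting the survivors) keeps the weight
sum at or below one by construction. No trinucleotide background correction
(exome-vs-genome) is applied by default; the fit operates on whatever
channel distribution the input carries. Dominance is the row argmax, with
exact ties resolved to the lexicographically smallest name and flagged. CN
signature extraction is out of scope: exposures arrive as an input matrix
and only the dominant rule and downstream statistics apply to them; a
48-channel dimension check (`validate_cn_catalog()`) is available when a CN
catalog is supplied.

**Association statistics.** Each signature gets its own 2x2
dominant-vs-cluster table (the per-signature adjusted p-values reported for
such analyses imply per-signature tests rather than one omnibus table).
Expected counts from the margins choose the test: Pearson chi-square without
continuity correction when all four are at least 5, otherwise the two-sided
Fisher exact test defined as the sum of hypergeometric probabilities no
larger than the observed table's — the convention of R's `fisher.test`,
stated explicitly because two-sided Fisher definitions differ. BH adjusts
within each signature family (SBS and CN separately; the joint family is a
defensible alternative, but separate families match how the two analyses are
reported). The bootstrap resamples patients with replacement within each
cluster — the only unit choice that preserves the sampling variability of
the dominant counts — and records per-signature counts over R = 1000
replicates (seed 123 by default). Replicate distributions are compared with
the two-sample Anderson-Darling k-sample statistic (midrank tie version,
essential for count data). Its asymptotic p interpolates the published
critical-value curves of the standardized statistic; outside the tabulated
range the p is capped at 0.25 or floored at 0.001, because the quadratic
interpolant is not trustworthy there. For combined sizes up to 12 an exact
permutation p over all splits replaces the approximation. Cohen's d uses
pooled n-1 SDs, the large-sample standard error
`sqrt((nx+ny)/(nx ny) + d^2/(2(nx+ny-2)))`, a central-t interval, and the
0.2/0.5/0.8 magnitude bins. Logistic models are univariate on the feature's
native scale (no covariates, no standardization — odds ratios are then per
unit of the feature, which for cell fractions makes them large but directly
interpretable), LGI coded 1, Wald intervals, Bonferroni within feature
family; quasi-complete separation is detected (non-convergence or a
diverging slope) and flagged rather than hidden. The correlation control
groups substitutions of hallmark genes by gene and pyrimidine-normalized
class and tests, per class, the Pearson correlation between occurrence count
and mean VAF across genes: a strong correlation would warn that substitution
differences between VAF-defined clusters are artifacts of the clustering
input itself.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` plants exactly the structure the pipeline is meant to
recover: two groups whose hallmark orders differ (genome instability first
vs last, immune evasion and inflammation early in the LGI order),
group-specific SBS mixtures drawn against a catalog, one dominant CN
signature per patient, and Gaussian features with group-shifted means.

Default values, chosen once:

* `vaf_base = seq(0.33, 0.27, length.out = 10)`: rank r maps to the r-th
  value. The narrow 0.06 range makes the largest between-group hallmark
  differences ~0.05-0.06 — the scale of the differences the analysis is
  designed to resolve (reported cluster differences in real cohorts are
  ~0.05). Larger ranges would make clustering trivially easy and the tests
  uninformative.
* `vaf_noise_sd = 0.015` on the per-patient hallmark means, plus
  per-mutation beta jitter with concentration `nu = 150` (SD ~0.037 at
  VAF 0.3). With ~8 mutations per hallmark (Poisson), the per-hallmark mean
  carries a total SD of ~0.02, which puts planted-group recovery around
  97-99% accuracy — separated but not caricatured.
* `muts_per_hallmark = 8` gives ~80 mutations/patient, comfortably above the
  50-mutation filter; dedicated fixtures lower it to exercise the filter.
* Synthetic gene names `<HALLMARK>_g<k>` and an emitted matching map remove
  any dependence on an unpublished real gene assignment; contexts are
  generated directly from the mixture spectrum (no FASTA needed), and half
  the records are emitted on the purine strand so strand normalization is
  always exercised.
* The signature catalog itself is synthetic (`synthetic_signature_catalog()`,
  names `sSBS*`): block-concentrated random spectra, well separated in L1,
  standing in for a curated catalog without shipping third-party data.

Not modelled, deliberately: clonal structure and subclonal VAF mixtures,
purity and copy-number distortion of VAF, per-cancer-type composition,
genuine biological correlation between mutation load and hallmark order.
Passing tests on these cohorts therefore demonstrate that the machinery
recovers planted structure under realistic noise — not that real tumors
satisfy the VAF-timing assumptions.

`generate_null_cohort()` copies every EGI setting onto the LGI group while
keeping labels, which is what the calibration tests feed: over 200 null
cohorts the fraction of adjusted-significant signature tests and
Bonferroni-significant features stays below 0.06, while a planted
relative-risk-3 dominant-CN enrichment at 300 patients per cluster is
detected in well over 90% of repeats.

## Numerical choices and degenerate inputs

* Golden-section weight search on [0, 1] with tolerance 1e-6; greedy stop at
  SSE improvement < 1e-3 (the refitting tool's published default).
* k-means degeneracy: fewer distinct points than k yields the distinct-point
  partition with WSS 0 and a `degenerate` flag instead of an error.
* Zero-margin contingency tables return p = 1 with a degenerate flag; a
  constant pooled sample in the AD test does the same.
* Constant features give OR = 1 with a degenerate flag; separation is
  flagged with the estimate reported as the bound reached.
* Writers emit full double precision; write-then-read round trips reproduce
  values to 1e-12.
* The Mann-Whitney comparison uses exact enumeration when both groups have
  at most 8 observations and no ties, and the continuity-corrected normal
  approximation with tie correction otherwise. The approximation tracks the
  exact p to about 0.01-0.02 at n = 8 — a property of the approximation
  itself, worth knowing when interpreting borderline p-values in small
  strata.

## Problem sizes used by the test and acceptance runs

Chosen as the smallest sizes at which each property is stable: cohorts of
200 per group for clustering recovery (accuracy and elbow selection are flat
well below that), 10,000 sampled mutations for mixture recovery (weight
error ~0.03), 200 null repeats at 100 per group for calibration, 50 repeats
at 300 per group for power, and bootstrap R of 100-200 inside tests versus
the 1000 default for analysis use.

## Known limitations

The clustering pipeline assumes the two-cluster structure it then labels;
with k forced elsewhere the EGI/LGI labelling and all downstream two-group
statistics are skipped. BH families, PCA scaling, the logistic feature
scale, and the refit trim/tolerance are all configurable because the
canonical choices are genuinely underdetermined; the defaults above are the
package's own and are stated wherever they matter. Cancer-type-stratified
analyses and survival endpoints are out of scope.
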