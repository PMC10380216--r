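---
title: "Methods and design of roiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of roiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`roiomics` analyzes region-of-interest (ROI) resolved tumor multi-omics:
negative-binomial-like probe counts from small transcriptomic ROIs (tROIs)
and log-normal label-free intensities from larger proteomic ROIs (pROIs),
nested within patients. This vignette explains the statistical machinery,
the parameters that matter, what the synthetic cohort does and does not
emulate, and the design choices made where the methodology was genuinely
open.

## Data model and containers

An `AnnotatedMatrix` couples a features × ROIs matrix with a per-ROI
annotation table (case, ROI kind, tissue, morphology, ordinal immune /
mucin / stroma scores in 0–3, TIL %, and the tROI → parent-pROI mapping)
and per-feature metadata. Missing proteomic cells are `NA`, never 0: a 0 is
a legitimate log2 intensity. All readers/writers round-trip missing cells
as empty fields.

## Transcript preprocessing

Probes are quality-controlled within each gene target: a probe is dropped
when its geometric mean across ROIs falls below 0.1 × the gene-level probe
geometric mean, or when it is a Grubbs outlier (α = 0.01, two-sided
critical value from the t quantile) among its gene's probes in ≥ 20% of
ROIs. The 20% occurrence rule and α follow platform convention; both are
arguments. Counts are floored at 1 before any geometric statistic — this
keeps logs defined at zero while leaving positive counts untouched, so the
closed-form values (e.g. LOQ of negatives (2, 8) = 16) hold exactly.

Gene counts are the geometric mean of the surviving probes. The per-ROI
limit of quantitation is GM × GSD² of the negative probes, with the GSD
computed from the population (divide-by-*n*) standard deviation of
natural-log counts; the sample variant changes LOQs by < 10% at 20
negatives and is not exposed. LOQ is reported but does not filter genes by
default (`loq_filter = TRUE` enables a majority-below-LOQ filter), since
the normalization chain does not depend on it.

Q3 normalization multiplies each ROI by
factor = GM(all ROI Q3s) / ROI Q3, so the geometric mean of Q3 values is
invariant — this is asserted to 1e−9 in the tests. Quartiles use linear
interpolation between order statistics (R's default type 7); the
convention is fixed so golden values are stable.

## Proteome preprocessing

"Centering around the global median" is implemented as per-ROI alignment
to the grand median of observed values. A single global shift would leave
between-sample offsets in place and would not normalize anything; the pure
global variant remains available (`per_roi = FALSE`). Features observed in
< 80% of ROIs are removed, then missing cells are imputed with
low-abundance draws: N(mean = 1% quantile of the ROI's observed values,
sd = median per-feature SD × `tune_sigma`). The σ estimator is a design
choice (the field's tools do not document theirs); it is recorded in the
`ImputationRecord` and parameterized. Two quantification tracks (LFQ-like
between-sample, iBAQ-like within-sample) share these operations.

## Single-sample gene-set scores

Scores are rank-based and sample-wise: features are ranked ascending, the
mean rank of the set members is rescaled against its attainable bounds
((n+1)/2 and (2N−n+1)/2) and centered, giving [−0.5, 0.5] with +0.5 when
the members are exactly the top-n features. Ties get average ranks, which
keeps scores invariant under permutations within tie groups. Only
directional (up) sets are supported; sets overlapping fewer than 10
measured features are removed before scoring — below that the rank mean is
too unstable to interpret.

## Consensus clustering and K selection

The matrix is z-scored per feature; each bootstrap replicate keeps 80% of
items and 80% of features, clusters with PAM (BUILD + SWAP, via
`cluster::pam`) on Pearson distance D = 1 − r, and the consensus matrix
accumulates co-clustering frequency conditioned on co-sampling. Final
labels cut a complete-linkage tree of 1 − M at K. Defaults (1000
replicates, 0.8/0.8, K = 2–10) are the field's standard settings; tests
and the pipeline scale replicates down (40–100) because the consensus
matrix of well-separated data saturates long before 1000.

Choosing K mechanizes the visual CDF inspection used in practice. The
delta-area rule alone (relative area increase ≥ 0.05) turned out to be
insufficient: resampled partitions of even structureless data keep gaining
CDF area with K, so every K passes. A candidate K must therefore also be
unambiguous — its proportion of ambiguous clustering (PAC: off-diagonal
consensus values in (0.1, 0.9)) must stay ≤ 0.1. With planted 3-cluster
data this selects K = 3; with structureless data no candidate qualifies
and the smallest K is returned. Both thresholds are arguments.

## Mixed-model differential expression

Every feature gets a Gaussian linear mixed model
y = β₀ + β₁x + u_patient + ε fitted by REML (`lme4`), with counts entering
as log2(x + 1). The patient random intercept absorbs the dominant
interpatient variance so that β₁ reflects within-patient contrasts.
P-values are Wald with a normal reference; at the simulation sizes used
(≈ 200 observations, 20 patients) the realized type-I error is ≈ 0.05
(asserted to lie in [0.03, 0.07]). Singular fits (variance estimate on the
zero boundary) fall back to OLS and are flagged — with a true zero patient
variance the estimates then agree with OLS exactly.

Significance rules differ per contrast, mirroring how such studies report
them: tumor-vs-NAT requires |β₁| ≥ log₂ 1.5 and BH-adjusted p < 0.05, and
only patients carrying both tissues contribute rows; ordinal scores
(immune, mucin, stroma) additionally require the per-level group means to
be strictly monotone in the declared direction with the extreme-level span
≥ log₂ 1.5 — the "tendency" is formalized as strict monotonicity of raw
level means on the log2 scale, and the fold change is measured between the
extreme levels rather than from the model coefficient (the most literal
reading; both quantities are reported). NAT ROIs and levels observed in a
single ROI are dropped first. Continuous covariates (TIL %) use the BH
rule only, since a 1-percentage-point unit carries no natural fold change.

## Enrichment

Overrepresentation uses the hypergeometric upper tail P(X ≥ k) against an
explicit universe — the universe is an argument because it legitimately
differs per analysis (shared symbols for cross-omic hit lists, all
quantified features otherwise). Pre-ranked GSEA ranks features by
β × (−log₁₀ p) (mean β for multi-group contrasts), computes the weighted
Kolmogorov–Smirnov running-sum ES, and obtains the null by re-drawing set
labels (default 1000 permutations) — the standard null for pre-ranked mode,
where no sample phenotype exists to permute. NES divides ES by the mean
|null ES| of matching sign. Gene-set size bounds default to [1, ∞).
Signed log2 coefficients (not linear ratios) feed the metric so down- and
up-regulation rank symmetrically.

## Cross-omic integration

tROI values are averaged within their parent pROI (arithmetic mean;
pROIs without children are excluded with a message, cross-case mappings
are an error), then each shared symbol or gene-set score is correlated
across matched pROIs (Pearson, two-sided t test, BH). Aggregated
normalized counts are used as-is, without z-scoring — the most literal
choice; correlation is scale-invariant per identifier anyway, which the
tests assert under affine rescaling.

## Heterogeneity screening

The CV (sd/mean) is computed per feature within each case's tumor ROIs —
NATs are excluded first so the screen is not driven by tumor-vs-NAT
differences, and cases with a single tumor ROI contribute nothing. CVs are
computed on the linear scale (counts; 2^log2 intensities): the CV of log
values is ill-defined near 0. A log option is retained for sensitivity
analysis. Selection is per-case quantile membership (type-7 quantile,
boundary ties included): bottom/top 20% in ≥ 4 cases for stable/variable,
or every eligible case for the strictest variable list. Membership is
invariant under monotone transforms of a case's CVs, so the linear-vs-log
choice mostly shifts borderline features. The screen runs post-imputation
for proteins, matching the matrix every other analysis uses.

## TME deconvolution

Per ROI, non-negative cell-type abundances β minimize
Σ_g [log₂(y_g + c) − log₂((Xβ)_g + b_g + c)]², the log-normal error model
appropriate for counts spanning orders of magnitude, with X a genes ×
cell-types profile matrix, b the per-ROI background (geometric mean of
negative probes, rescaled by the ROI's Q3 factor when fitting normalized
counts) and pseudocount c = 1. The solver is projected Gauss–Newton with
backtracking (tolerance 1e−8 on the objective decrease, cap 1000
iterations; the objective is non-increasing by construction). On exact
data it matches linear NNLS to 1e−3 and recovers noiseless mixtures to
1e−4 relative error. No published profile matrix is redistributed: the
generator ships a synthetic block-structured profile, and any genes ×
cell-types CSV is accepted. Co-localization clusters cell types by k-means
on z-scored abundance profiles and reports their correlation matrix.

## Survival

Features are summarized as the patient mean over tumor ROIs (NATs
excluded), then fitted one at a time in a stratified Cox model with Efron
tie handling — strata allow different baseline hazards per treatment
without estimating a treatment effect. Monotone-likelihood fits are
flagged and their intervals reported unbounded. At 7 patients the screen
carries an explicit small-sample warning; calibration claims (null HR
behavior, CI coverage ≥ 90% at log HR 0.7) rest on repeated simulated
cohorts of 150–200 patients.

## The synthetic cohort

The generator emulates the study design the pipeline assumes: 7 patients,
12 tROIs each (2 NAT), 2–6 pROIs (one NAT where a patient has ≥ 3),
tROIs mapped to parent pROIs, ordinal scores and TIL %. Counts are
negative binomial (dispersion 0.15) around gene baselines drawn
log-uniformly over three orders of magnitude — heavy-tailed enough to
exercise Q3's robustness — with 5 probes per gene (±0.15 log2 probe
effects), 20 negative probes (mean 3), and per-ROI depth factors
(0.2 log2 SD). Protein intensities are log-normal (20–30 log2 range,
0.4 log2 noise). Interpatient structure is planted as per-feature,
per-patient effects (0.5 log2 SD) — deliberately feature-specific, because
a global per-patient intercept would be removed by Q3/median normalization
and could not drive clustering, contradicting the patient-dominant
structure the analysis is meant to detect.

Planted truth: tumor-vs-NAT shifts (default ±1 log2; the DE recovery
analyses use ±2, i.e. 4-fold) on 20 genes and 20 proteins; immune-score
gradients (0.5 log2/step) on 15 genes; TIL slopes (0.1 log2 per
percentage point, sized for recoverability from ~20 tumor pROIs) on 15
proteins; 8×
variance inflation on 15 genes and proteins; 20 cross-omic pairs driven by
a shared per-pROI latent factor whose SD (1.2) was chosen once, from the
variance budget of the other components, to put the aggregated Pearson r
near 0.8; Dirichlet cell mixtures (patient-level means, concentration 30)
behind a dedicated 100-gene marker block; and exponential survival with
patient log hazard = 0.7 × the standardized patient-mean expression of a
designated shared gene, independent censoring, administrative cutoff at
15 years. Missingness is injected by an intensity-dependent logistic
(midpoint 22, slope 1.2), and a bisection helper calibrates the midpoint
to any requested overall missing fraction.

What the generator does not emulate: spatial coordinates or autocorrelation
beyond ROI identity, probe-level sequence artifacts, batch effects,
tumor-purity gradients, correlated planted categories (each feature is
planted in at most one role), or non-Gaussian protein error. Passing
recovery tests therefore demonstrates that the estimators find the
structure they model, at realistic sizes and noise — not that real tissue
obeys that model.

## Problem sizes and numerical conventions

Tests and the acceptance script run cohorts of 300 genes × 5 probes, 300
proteins, 100 deconvolution genes (≈ 84 tROIs, ~25 pROIs), consensus
clustering with 40–100 replicates, GSEA with 50–1000 permutations, 1000–
2000 mixed-model null fits and 200 Cox replicates — sizes chosen so the
full suite completes in a few minutes on one core while keeping
Monte-Carlo error well inside the asserted bands. All randomness flows
through explicit seeds; RNG state is restored after every seeded
operation, so library calls never perturb user code. Ties break
deterministically everywhere (average ranks in scores, lowest index in
PAM, type-7 quantiles), and every stochastic stage records its seed in its
provenance JSON.

## Known limitations

Wald tests with a normal reference are mildly liberal for very few
patients (the 7-patient cohort analyses are descriptive; calibration is
established at 20 patients). The PAC threshold for K selection is a
heuristic and, like any consensus criterion, can under-split data with
nested cluster structure. The deconvolution model assumes an additive,
gene-independent background per ROI. The imputation model is
single-draw — it does not propagate imputation uncertainty into downstream
standard errors.
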