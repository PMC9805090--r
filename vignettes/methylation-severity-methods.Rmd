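---
title: "Methods: differential methylation analysis of MS severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation analysis of MS severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
`msewas` pipeline, the default parameters and why they were chosen, the
assumptions of the synthetic cohort generator, and the numerical design
decisions that are not obvious from the function reference.

## Study design the pipeline targets

The pipeline analyses whole-blood DNA methylation (EPIC-style beta
values) from a relapse-onset multiple sclerosis cohort phenotyped
longitudinally for severity. The canonical configuration is 235
patients, labelled by the extremes of the severity distribution
(119 mild, 116 severe), with visit-level EDSS histories spanning at
least five years. All defaults in `simulation_config()` mirror this
design; every dimension is configurable.

## Severity phenotyping

EDSS is an ordinal disability scale that increases with age regardless
of severity, so raw EDSS comparisons confound age and disease course.
The age-related severity score (ARMSS) removes the age trend by ranking
a patient's EDSS within an age-matched reference population:

* `armss_score()` returns 10 times the mid-rank fraction, the mean of
  the "at or below" and "strictly below" fractions of the reference
  EDSS distribution in the integer-age stratum. The mid-rank treatment
  makes the score well-defined for tied EDSS values, bounded in
  [0, 10], and monotone in EDSS at fixed age.
* `longitudinal_armss()` drops relapse-associated visits (EDSS spikes
  during relapse reflect transient inflammation, not accrued
  disability) and takes the *median* per-visit score; the median is
  robust to single mis-scored visits.
* Eligibility (`check_eligibility()`) requires at least 5 years of
  follow-up and at least 3 relapse-independent scores, so the median is
  estimated from a meaningful trajectory.
* `classify_severity()` labels scores at or below the cohort's 20th
  percentile mild and at or above the 80th percentile severe, with the
  middle excluded. Percentiles use R's default type-7 linear
  interpolation; both cut points are inclusive ("at or"), which is the
  convention that makes a score exactly on the threshold an extreme. A
  degenerate distribution (both percentiles equal) yields all-excluded
  with a warning rather than arbitrary labels.

Extreme-tail sampling trades sample size for contrast: effect sizes in
whole blood are small (a few percent methylation), and comparing tails
roughly doubles the group separation relative to a median split.

## Preprocessing

Beta values are the fraction of methylated signal, bounded in (0, 1)
and heteroskedastic near the boundaries; M-values
(`beta_to_m()`, the logit2 transform) are unbounded and closer to
homoskedastic, so all linear modelling happens on M-values while effect
sizes are reported on the interpretable beta scale. Betas are clipped
to `[1e-6, 1 - 1e-6]` so the transform is finite and invertible.

* `filter_probes()` removes probes by six ordered rules (detection
  p > 0.01 in ≥ 5% of samples, bead count < 3 in ≥ 5%, non-CpG,
  SNP-related, multi-hit, non-autosomal). Each removed probe is
  attributed to the *first* rule that catches it so the report's counts
  sum to the total — the usual convention in array QC reports.
* `filter_samples()` removes samples whose failed/successful probe
  ratio exceeds 0.1 (strict).
* `bmiq_normalize()` implements beta-mixture quantile normalization of
  the type-II probe chemistry onto the type-I distribution. Both
  design types are fitted per sample with a three-state
  (unmethylated / hemimethylated / methylated) beta mixture via EM with
  moment-matched component updates and a deterministic quantile-split
  initialization, so results do not depend on RNG state. U- and
  M-state values are mapped by state-wise beta-CDF quantile matching;
  the hemimethylated cluster is shifted and dilated between
  *gap-preserving* anchors — the empty intervals separating it from the
  flanking clusters in the input are carried over to the output. An
  earlier draft stretched the middle cluster across those gaps, which
  distorted mid-range betas by up to 0.24 when the two designs already
  agreed; the gap-preserving rule reduces that worst case to ≤ 0.03.
  EM convergence is declared at a relative log-likelihood change below
  `1e-4`; a non-convergent sample passes through unchanged with a
  warning rather than receiving a half-converged transform.
* `svd_batch_detect()` row-centres the M-value matrix, computes the
  SVD, and tests each leading right singular vector against each
  candidate technical factor (ANOVA for categorical, Pearson for
  continuous), flagging pairs at p < 0.01.
* `combat_correct()` wraps parametric empirical-Bayes location/scale
  batch adjustment on M-values. One limitation is documented rather
  than hidden: genuine empirical-Bayes ComBat is *not* numerically
  idempotent. Shrinkage of per-batch estimates toward their priors
  leaves sampling-noise residuals of order σ/√n, which a second pass
  partially removes; at realistic sizes the second-pass change is
  ~0.04 M-units, an order of magnitude below the batch effects being
  removed. The test suite therefore checks the attainable contraction
  property (second-pass change ≪ first-pass change; batch means
  equalized within 0.05 M) instead of exact idempotence.

## Differential methylation at positions

`test_dmps()` regresses severity group on each probe's beta value plus
covariates (logistic, the default) or the probe's M-value on group plus
covariates (linear), reporting the Wald p of the methylation/group
term. The effect size is always the raw beta difference, severe mean
minus mild mean, so `delta_meth > 0` means hypermethylated in severe.

Two numerical details matter:

* The logistic predictor is standardized internally. The Wald p-value
  is invariant under linear rescaling of the predictor, but the raw
  slope is not: beta values have per-probe SDs of ~0.02, so unscaled
  slopes of magnitude 50 are *normal*, and any magnitude-based
  separation heuristic would misfire. After standardization,
  `|coef| > 15` really does indicate (quasi-)separation, and such fits
  fall back to a ridge-penalized IRLS fit flagged
  `"separation_penalized"`. Without this, ~6% of null probes were
  silently penalized and the null type-I rate deflated to 0.02;
  with it, permuted-label calibration sits at ~0.047 against the
  nominal 0.05.
* Constant probes cannot carry information and get p = 1 with a
  `"constant"` flag rather than an `NA` that would silently shrink the
  multiple-testing family.

Multiplicity is controlled by Benjamini–Hochberg FDR (`bh_fdr()`,
delegating to `stats::p.adjust`). `filter_dmps()` keeps FDR < 0.05
(strict) and |Δβ| > 0.01 (strict); "major" DMPs are those whose |Δβ|
reaches 0.05 after rounding to three decimals, so a table-printed
`0.050` counts as major.

`match_pairs()` supports a matched-pair sensitivity analysis: mild and
severe samples are 1:1 age-matched by repeatedly pairing the *globally*
closest pair within a ±2-year cap. Global greediness matters: matching
mild samples in input order can consume a severe sample that a later
mild sample needed, producing fewer pairs.

## Differential methylation at regions

Kernel and bump-hunting region callers lose power when effects are a
few percent methylation, so `call_dmrs()` uses a transparent
proximity/direction rule: probes with FDR < 0.01 (strict) are sorted
by position within chromosome and chained into maximal runs where every
adjacent pair is ≤ 1000 bp apart (inclusive) and shares the effect
sign; a sign flip splits the run at the flip. Runs of ≥ 2 CpGs are
regions, with `width = end - start` (the span between first and last
member). The rule is simple enough to verify against an exhaustive
enumeration oracle, which the test suite does.

## Cell-type deconvolution and cell-specific effects

Whole blood is a mixture of leukocyte types with distinct methylomes,
so bulk group differences can reflect either within-cell-type
methylation change or composition change. `estimate_proportions()`
fits each sample's marker-probe betas as a non-negative combination of
reference profiles (non-negative least squares, renormalized to sum to
one).

`cell_specific_dmps()` asks the sharper question — in *which* cell type
does methylation differ? Per probe it fits

```
M ~ 0 + w_1 + ... + w_K + w_1:severe + ... + w_K:severe
```

The model is deliberately fitted *without an intercept*: because the
proportions sum to one they span the intercept, and dropping it keeps
the design full-rank while retaining an interaction coefficient for
*every* cell type. The more common alternative — dropping one cell
type as a baseline — yields interaction terms interpretable only as
contrasts against the baseline type; the no-intercept parameterization
gives each type its own directly interpretable severity interaction,
which is what a per-cell-type csDMP count needs. The genome-wide
threshold is p ≤ 9e-8 (inclusive), the standard array-wide
significance level.

## Targeted mQTL analysis

Methylation at a CpG can be under local genetic control; a
severity-associated CpG driven by genotype would be confounded by
population structure. `genotype_qc()` applies the standard filters in
a fixed order (call rate < 95%, MAF < 0.05, HWE p < 1e-5,
monomorphism, non-autosomal), attributing each SNV to the first rule
that catches it; the HWE test (`hwe_test()`) uses the 1-df chi-square
with an exact enumeration branch when the smallest expected genotype
count is below 5. `mqtl_scan()` then takes each major DMP, collects
SNVs within an inclusive ±5 kb cis window, prunes them for linkage
disequilibrium (greedy, visiting by descending MAF), tests each
independent SNV with a Kruskal–Wallis rank test (betas are bounded and
non-normal, so a rank test is the conservative choice), and refits the
severity association jointly with the best genotype to check that the
methylation signal survives adjustment.

## Methylation age

`clock_model()` represents any linear epigenetic clock (weights,
intercept, optional monotone affine calibration). `clock_age()`
requires ≥ 90% of clock CpGs and imputes the missing ones with the
cohort mean of the present clock CpGs — a documented, reported
imputation rather than silent probe dropping. Methylation age
acceleration (`compute_maa()`) is the residual of regressing
chronological age on methylation age; this direction is the package's
reported convention, and the more common reverse regression is
available via `direction = "methyl_on_chron"` because the residuals
differ and should never be silently conflated. Group comparisons
(`compare_maa()`) gate between t and Wilcoxon tests on a Shapiro–Wilk
normality check.

## Severity classification

Three models are compared on one stratified 70:30 split
(`split_cohort()`, training takes `floor(0.7 n)` per label stratum; a
235-sample cohort yields 164/71):

1. a clinical elastic net (first-symptom site indicators plus onset age),
2. a genome-wide methylation elastic net, and
3. a univariate logistic model on the weighted methylation risk score
   (wMRS), `sum_i z_i * Δβ_i` over discovery DMPs, with z-scores
   standardized by *training-set* means and SDs only.

Elastic-net hyperparameters are tuned by stratified k-fold
cross-validated deviance over an alpha grid, ties going to the larger
lambda (the sparser model). The implementation delegates the convex
optimization to coordinate descent (`glmnet`) with a tight convergence
threshold (`1e-12`) and exact coefficient interpolation, and the test
suite pins it to an unpenalized `glm()` at lambda = 0 within 1e-4.
`compare_models()` hard-errors on any train/test overlap; all tuning,
fitting and wMRS standardization constants are computed from training
samples only. AUC is the normalized Mann–Whitney statistic (ties count
one half) with severe as the positive class.

## The synthetic cohort generator

Real severity cohorts of this design are access-controlled, so the
package ships a generator (`simulate_cohort()`) whose defaults *are*
the study conditions and whose ground truth is machine-readable:

* **Mixtures.** Each sample's beta profile is a Dirichlet-weighted
  mixture of six leukocyte reference profiles (granulocyte-dominated
  concentrations approximating whole blood), so deconvolution has a
  true answer (`truth$cell_proportions`).
* **Planted DMPs.** Group effects of configurable size (default 0.05
  beta, alternating sign) are added to severe samples at 50 probes;
  with `cell_specific_effect = TRUE` the effect scales with one cell
  type's proportion so only the interaction model can attribute it.
  Three planted DMP pairs are repositioned as same-chromosome
  neighbours under 1000 bp with matching sign, forming truth DMRs.
* **Clock CpGs** are age-linear with an invertible synthetic clock
  shipped alongside (`cohort$clock`).
* **mQTLs.** Genotypes are drawn in Hardy–Weinberg proportions and
  planted pairs shift the CpG's M-value additively per alternate
  allele within a cis window.
* **Technical structure.** Batch shifts/scale inflation and Gaussian
  noise are applied on the M (logit) scale — noise on the bounded beta
  scale would be heteroskedastic in an uncontrolled way and could
  leave the unit interval.
* **Histories** are generated to satisfy the eligibility rules by
  construction, with severe trajectories drawn high-for-age.

Everything derives deterministically from `config$seed`. Limitations
worth stating: probe-probe correlation beyond the planted DMRs is not
modelled; noise is homoskedastic per batch on the M scale, while real
arrays show probe-dependent variance; and the reference profiles are
caricatures (strong bimodal markers), so deconvolution is easier than
on real blood. These simplifications make truth recovery checkable
without making any stage trivially easy — noise, mixing and batch
structure still attenuate and confound the planted signals.

## Problem sizes

Default problem sizes (2000 probes, 200–235 samples) are the package's
own desk-scale choice: large enough that FDR control, LD pruning and
cross-validated tuning behave asymptotically as intended, small enough
that the full pipeline runs in seconds to minutes on one CPU. All
sizes scale up by configuration.
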