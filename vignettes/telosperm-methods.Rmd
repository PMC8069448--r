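---
title: "Models and methods behind telosperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind telosperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(telosperm)
```

telosperm studies the relationship between telomere length and semen
quality from three angles: a direct relative measurement of sperm telomere
length (STL) by qPCR, an indirect genetic proxy (the "teloscore" built from
11 telomere-length GWAS SNPs), and single-SNP association models. This
vignette explains each model, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic cohort generator does and does
not emulate.

## Relative telomere quantification

STL is the ratio of telomere-repeat abundance to a single-copy reference
gene (albumin), measured on the same sample. Both targets are amplified in
triplicate and each plate carries a 7-point 1:2 dilution standard curve
(20 ng down to 0.3125 ng) per target.

**Standard curves.** `fit_standard_curve()` regresses Ct on log10(input
mass). The amplification efficiency is `E = 10^(-1/slope)`; perfect
doubling corresponds to a slope of `-1/log10(2) ≈ -3.32` and `E = 2`. The
calibrator Ct is the *fitted* value at 5 ng rather than a raw 5 ng well:
the fit pools the information of all seven dilution points and makes the
calibrator insensitive to a single noisy well. Curves are fitted per plate
by default so that plate-level shifts cancel in the ratio; a pooled mode
exists for runs whose plates lack their own dilution series. Fits with
non-negative slope, fewer than three distinct masses, or efficiencies
outside (1, 4) are rejected.

**Triplicate QC.** Two discard rules are implemented in
`qc_triplicates()`. The *literal* rule removes any well deviating from the
triplicate mean by more than 5% of the triplicate's standard deviation.
This rule is pathologically stringent: for any non-constant triplicate the
extreme wells always deviate by roughly one SD, i.e. twenty times the
cut-off, so almost every noisy triplicate is discarded wholesale (the test
suite demonstrates this). Because the rule as stated is unusable on real
noise, the threshold and the rule itself are configurable, and a
*CV* rule (discard triggered when SD/mean exceeds 5%; the most deviant
well is dropped and the set re-checked) is provided and used as the
pipeline default in `quantify_stl()`. SDs use the sample (n−1)
denominator. Sets reduced below two surviving wells are flagged unusable
and the subject's ratio is set missing rather than guessed.

**Pfaffl ratio.** With per-target efficiencies `E_tel`, `E_alb` and
calibrator Cts taken at 5 ng,

    STL = E_tel^(Ct_cal,tel − Ct_tel) / E_alb^(Ct_cal,alb − Ct_alb)

which reduces to the familiar `2^(ΔCt_tel − ΔCt_alb)` when both
efficiencies are exactly 2 (a unit-tested identity). The ratio is
log-transformed with the natural log for analysis; the base only rescales
regression coefficients by a constant and is documented rather than
configurable. When STL is used as an *exposure*, plate effects are removed
by centering log STL on its plate mean (`residualize_on_plate()`,
equivalent to OLS residuals on plate indicators); when log STL is the
*outcome*, plate enters the model as a random intercept instead.

**Primer product model.** The telomere primers amplify each other: the
predicted amplicon is found by the maximal perfectly complementary
3'-terminal overlap of the two primers (antiparallel Watson–Crick
pairing), with product length `len(a) + len(b) − k`. The shipped Telg/Telc
pair overlaps by 3 bases and predicts a 79 bp product. Internal-mismatch
and thermodynamic models are out of scope, as is verifying the genomic
albumin amplicon, which requires a genome template.

## Genotype quality control

Subjects are filtered on call rate: a subject is kept when at least 80% of
panel SNPs are called (ties at exactly 80% survive; strictly lower
discards). Per-SNP call rates are reported but no SNP is auto-dropped.
Hardy–Weinberg equilibrium is tested per SNP with the 1-df chi-square
goodness-of-fit test against expectations from the observed allele
frequency — the standard choice at cohort scale with common alleles — with
an exact conditional test available for rare alleles; no particular test is
asserted as "the" correct one and the α used for screening is the user's.
Duplicate-sample concordance compares calls as unordered allele pairs
("C/A" ≡ "A/C"; all calls are normalized on read).

Dosage encodings: *additive* counts effect alleles (0/1/2); *codominant*
forms genotype-class factors with the major-allele homozygote as reference.
Genotype classes absent from an analysis sample simply drop at model time,
so a SNP whose minor homozygote never occurs contributes a single contrast.

## Telomere genetic scores

The unweighted teloscore sums effect-allele dosages over the panel (range
0–22 for 11 SNPs); the weighted score multiplies each dosage by its
literature effect size before summing. Weights are deliberately taken from
published GWAS estimates and never re-fit in the analysis cohort, to avoid
overfitting. Because partially genotyped subjects would otherwise have
deflated scores, the scaled variants divide by the number of genotyped SNPs
and multiply by the panel size; the same formula is applied to the weighted
score (no separate convention is established for it). The shipped panel's
effect alleles, weights and European minor-allele frequencies are
literature-derived defaults and explicitly configurable — the panel config
is the single source of truth, and none of these constants is hard-coded in
scoring logic.

Quintile categorization of any continuous exposure is rank-based: category
boundaries at the 20/40/60/80th sample percentiles, ties assigned to the
lower category, category 1 (lowest) the reference. This convention is fixed
for reproducibility; other percentile definitions move a handful of
boundary subjects but none of the package's conclusions.

## ABCD semen-quality scores

Each of four parameters (sperm concentration, progressive motility, total
motility, normal morphology) is banded against reference percentiles:
A below the 5th, B from the 5th up to the 50th, C from the 50th up to the
95th, D at or above the 95th. The quoted band definitions are
interval-ambiguous at the boundaries, so the half-open convention
`[p5, p50)`, `[p50, p95)` was fixed and is unit-tested; A is strictly below
p5. Default centiles are the WHO 2010 reference distribution (5th/50th/95th
for fertile men); they ship as a config table and can be replaced by
cohort-empirical percentiles, with the choice recorded by the caller.

The bands are converted to numbers in one of two modes. The default
*integer* mode assigns 1/2/3/4 to A/B/C/D. The *interpolated* mode adds the
value's linear position within its band (band A interpolates from 0, band D
is capped just below 5), always flooring back to the integer code. The
construction of a pseudo-continuous band value from a density distribution
admits several readings; both modes are explicit reconstructions, the mode
is recorded in the output, and neither is claimed to be uniquely correct.
The composite ABCD score sums the four parameter values (4–16 in integer
mode) and ABCD_mot sums the two motility values (2–8); higher is better.

## The association scan

All models are linear regressions adjusted for age (years, continuous) and
smoking (yes/no), complete-case per model with the n used recorded per
record. The design is:

* plate-residualized log STL, linear and in quintiles, against the nine
  semen parameters and the two ABCD composites;
* the scaled unweighted and weighted teloscores, linear and in quintiles,
  against the same outcomes plus log STL;
* each panel SNP, additive and codominant, against the same outcomes plus
  log STL.

Models with log STL as the outcome include the reaction plate as a random
intercept, fitted by REML through lme4; the estimation contract is
behavioral — when the plate variance is zero the fixed effects equal the
OLS fit (tested to 1e-6) — leaving the solver free. Fixed-effect inference
is Wald-type: t-based for OLS records, normal-based for mixed-model
records (likelihood-ratio alternatives are not implemented; at n ≈ 600 the
difference is negligible and the choice is recorded here). Skipped models
(too few complete cases, single-class exposures) are logged in the
`skipped` attribute, never silently dropped, so the record count is an
exact function of the design enumeration.

Multiple testing follows the SNP-scan convention 0.05/33 ≈ 0.0015 (11 SNPs
× three inheritance contrasts). The Bonferroni flag applies to SNP records
only; STL and teloscore records carry the nominal flag, and both thresholds
are stored as attributes on the results. Note that 0.05/33 controls the
family-wise error of one 33-test family: across a full multi-outcome scan
(~390 SNP records) the expected number of null records below 0.0015 is
about 0.6 per scan, so occasional sub-threshold records are expected under
the null — a property of the correction itself, not of the implementation.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable, calibratable
and power-analyzable without individual-level data. It emulates, at the
level of first and second moments:

* HWE genotypes at configurable MAFs with independent per-genotype
  missingness (default 2%, matching typical assay call rates);
* a latent log telomere ratio that is additive in effect-allele count
  (default 0.05 per allele, residual SD 0.3) — missing dosages contribute
  their expectation (2 × effect-allele frequency) during generation only;
* qPCR plates: 13 subjects per 96-well plate (6 sample wells plus 14
  standard wells), per-plate-and-target Ct offsets (SD 0.15 cycles),
  well noise (SD 0.15 cycles), and true efficiencies 1.9 (telomere) and
  2.0 (albumin). The Ct model is the exact inverse of the quantification
  model, so at zero noise the pipeline reproduces the latent values to
  machine precision — a deliberate design choice that turns the
  quantification stage into a testable bijection. Because each plate's
  standard curve shares the plate offset, plate effects cancel through the
  calibrator and only curve-estimation noise survives as residual plate
  structure;
* ages from a normal (mean 34.8, SD 7.5) truncated to 18–59, 32% smokers;
* semen parameters as independent linear functions of age (defaults set to
  the magnitudes observed in clinical cohorts, e.g. −0.31 percentage
  points of progressive motility per year) plus Gaussian noise, clipped to
  their valid ranges; the telomere-to-sperm effect defaults to zero, the
  null scenario. Smoking is carried as a covariate but given no generative
  effect.

What it does **not** emulate: linkage disequilibrium between SNPs,
population stratification, and the joint distribution of semen parameters
(each is generated marginally, so e.g. progressive motility is not
constrained below total motility). Range truncation is by clipping, which
slightly biases means and slopes when the configured mean sits within
about two SDs of a bound — negligible at the defaults, documented for
extreme configurations. Consequently, passing calibration tests on this
generator demonstrates correctness of the statistical machinery under the
assumed structure, not robustness to the correlation patterns of real
semen data.

Seeding: one master seed per cohort, with fixed per-stage sub-seeds derived
from it, so identical configs give byte-identical cohorts and each stage
can be regenerated independently.

## Problem sizes used in the test suite

Calibration and coverage checks in the test suite use 500 replicate
cohorts of 599 subjects for the null-scan calibration and the
parameter-recovery coverage, 200 lighter replicates for single-model
type-I checks, and large single draws (10^5–2×10^5 genotypes) for
frequency checks; these sizes give Monte-Carlo standard errors comfortably
inside the asserted tolerance bands. Unit examples run at toy scale.

## Known limitations

* The literal triplicate rule is faithful to its description but unusable
  on realistic noise; the CV rule is the practical default, and the two can
  disagree on which wells survive.
* Mixed-model p-values are normal-approximation Wald tests; small-sample
  degrees-of-freedom corrections (Satterthwaite, Kenward–Roger) are not
  implemented.
* The weighted-score units follow whatever the panel weights use; only
  relative magnitudes matter downstream.
* `quantify_stl()` assumes each subject's wells sit on a single plate, as
  laid out by the generator and by the standard plate design.

## A worked miniature

```{r example, message = FALSE}
cfg <- cohort_config(n_subjects = 150, seed = 42)
cohort <- simulate_cohort(cfg)
res <- analyze_cohort(cohort)
dplyr::filter(res$records, exposure == "rs2736100", outcome == "log_stl")
```

The additive record estimates the change of log STL per effect allele of
the SNP; with the default generator settings (0.05 per allele) the
confidence interval should usually cover 0.05.
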