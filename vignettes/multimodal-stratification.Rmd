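---
title: "Multimodal biomarker stratification of dementia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal biomarker stratification of dementia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixstrat)
```

## The problem

Memory-clinic populations mix several pathologies that look alike in the
office: Alzheimer-type neurodegeneration, small-vessel ischemic white-matter
disease, and — most often at autopsy — both at once. A clinical diagnosis
made from an office visit (history, neuropsychology, routine FLAIR MRI)
systematically under-calls this *mixed dementia*, because white-matter
hyperintensities on FLAIR are nonspecific and CSF chemistry is not part of
the routine work-up. Biological stratification replaces the clinical call
with two quantitative severity axes:

* **Alzheimer axis** — CSF phosphorylated tau (Ptau, elevated in Alzheimer
  pathology) and the amyloid-beta 42/40 ratio (lowered);
* **Vascular axis** — mean diffusivity (MD) of white matter from diffusion
  tensor imaging, summarized as a z-score against controls, which detects
  microstructural damage that FLAIR cannot grade.

Crossing the two dichotomies partitions patients into four quadrants:
neither axis positive is leukoaraiosis (LA, white-matter signal without
microstructural damage or cognitive abnormality); Alzheimer axis only is
AD; vascular axis only is subcortical ischemic vascular disease (SIVD);
both is mixed dementia (MX). Patients with large-vessel or strategic
infarcts (MI) are recognized by the infarct flag directly and bypass the
quadrants. `classify_dichotomy()` implements exactly this rule;
`classify_feature_matrix()` offers a complementary nearest-archetype
matcher over a nine-feature sign table (clinical signs, cognitive deficits,
MRI and CSF positivity per group).

## Scores

Cognitive tests arrive as standardized T-scores (population mean 50, SD
10). Domain composites are plain means of the available tests in a domain
(`domain_composite()`), and the overall composite is the mean of the
available domain composites (`overall_composite()`), reporting how many
domains contributed. Missing tests within a domain are simply dropped — a
deliberate, configurable choice (`min_tests`, default 1): composites stay
comparable across patients with incomplete batteries at the price of
unequal precision.

Diffusivity is normalized with `fit_control_reference()` /
`md_zscore()`: z = (MD − control mean) / control SD, with the sample SD on
the n − 1 denominator. Normal is then near zero and damaged white matter
sits in the 1–3 range. Z-scoring a control sample against its own
reference yields mean 0 and SD 1 exactly, and the transform is affine
equivariant — rescaling raw MD (e.g. between scanner protocols) together
with its reference leaves z unchanged. The pipeline exposes no per-coil
harmonization beyond this: if acquisition batches differ, the caller
should fit one reference per batch.

## Thresholds

No numeric cut-points for this stratification are published; "high" and
"low" are qualitative in the source dichotomy. The defaults in
`thresholds()` are therefore package choices, selected once to fall
between the published group means and documented as such:

| cut | default | rationale |
|---|---|---|
| `md_z_high` | 2.0 | between vascular groups (SIVD 2.94, MX 3.20) and non-vascular (AD 0.74, LA 1.02) |
| `ptau_high` | 68 pg/mL | between AD/MX (87.75/118.86) and SIVD/LA (47.43/46.05) |
| `ab_ratio_low` | 0.07 | between the amyloid-positive (0.05) and negative (0.10) generator defaults |
| `t_memory_low`, `t_executive_low` | 40 | one population SD below the T-score mean |
| `albumin_index_high` | 7 | feature matcher only; blood–brain-barrier leakage |

Positivity holds at the exact cut (`>=` for high markers, `<=` for low
ones), and every cut is config-overridable. The Alzheimer axis combines
its two analytes under `ad_axis_rule = "either"` by default — the source
method uses both analytes without stating the combination logic, and
"either" is the sensitive choice for a screening-style stratification;
`"both"`, `"ptau_only"` and `"amyloid_only"` are available. The feature
matcher breaks score ties by the fixed precedence MX > SIVD > AD > LA,
preferring the treatment-relevant dual-pathology call.

## The synthetic cohort

No patient-level data are available, so the package ships a generator
whose defaults *are* the study conditions: per-group means and SDs for
age, T-memory, T-executive, MD z, MMP-1, MMP-10 and Ptau equal the
published group-summary table for LA, MX, SIVD, AD and controls, and the
default group sizes are the published biological distribution (SIVD 53,
AD 25, MX 22, MI 18, LA 29) plus 25 controls (control count unpublished;
25 chosen as a typical single-center imaging-control panel).

Variables with no published parameters carry documented defaults: the
amyloid ratio is 0.05 (SD 0.015) in AD/MX versus 0.10 (SD 0.02) elsewhere,
making the Alzheimer axis separable; MMP-3 is ordered so MX is elevated
while AD is not; attention/language/speed T-scores and the albumin index
are plausible values consistent with each group's qualitative profile.
Binary clinical signs follow the published sign table with `+` as 0.8 and
`−` as 0.2; controls have low sign rates. The MI group, absent from the
summary table, gets SIVD-like continuous values and infarct probability 1
(0.02 in other patient groups — occasional incidental infarcts — and 0 in
controls).

Numerically, each continuous variable is drawn from a normal restricted to
its plausible range (T-scores [0, 100], positive CSF analytes, ratio in
(0, 1), age [18, 110]) by inverse-CDF sampling, and the location of the
underlying normal is calibrated by root-finding so that the mean of the
*restricted* distribution equals the configured mean. Plain
truncate-and-redraw sampling would inflate means wherever a bound sits
within a few SD of the target — for MX Ptau (mean 118.86, SD 57.82,
bounded at 0) by about +2.9 pg/mL, more than the 3-standard-error
calibration tolerance at n = 10,000 — so calibration is what makes the
generator honest about the published means. Inverse-CDF sampling also
consumes exactly one uniform per draw, which keeps runs byte-reproducible
under a seed. Within a group, variables are drawn independently: no
covariances are published. This is the generator's main simplification —
real cognitive scores, diffusivity and CSF markers are correlated within
patients, so passing tests on synthetic cohorts demonstrate the pipeline's
arithmetic and rule logic, not classifier performance on real data.

The clinical labels of a synthetic cohort are perturbed through a
row-stochastic confusion matrix P(clinical | biological), emulating the
observed clinical-to-biological reassignment: the default is the identity
except that biological MX maps to clinical SIVD/AD/MX with probabilities
0.27/0.36/0.37, which makes the expected clinical margins approximate the
published clinical counts (59, 33, 9 for SIVD, AD, MX). These values are
documented, not fitted.

## Statistics

Group differences use nonparametric tests throughout: a tie-corrected
Kruskal–Wallis omnibus per variable (chi-square approximation on k − 1
df), and two-sided Mann–Whitney U tests for all group pairs. The pairwise
p-values are corrected within the family of pairs *per variable* — the
omnibus already spans groups, and cross-variable families would conflate
unrelated hypotheses. The correction defaults to Holm's step-down
(uniformly more powerful than Bonferroni at the same family-wise error
rate; the source states only that a correction was applied), with
Bonferroni available. Mann–Whitney p-values are exact by enumeration when
both groups have at most 20 observations and no ties; otherwise the normal
approximation with tie and continuity correction is used. U is oriented to
the first group (number of pairs with x > y, ties half). Degenerate
Kruskal–Wallis input — every pooled value identical — is reported as H = 0,
p = 1 by convention, since the tie correction is undefined there.

## Pipeline and determinism

`run_pipeline()` chains the stages: simulate (or ingest and validate) a
patient table, derive the overall composite and, if needed, `md_z` from a
raw `md` column z-scored against the table's own controls, classify every
record, and assemble the clinical-versus-biological cross-tabulation
(patients only), per-group summaries, pairwise tests and a manifest that
echoes every threshold, size and seed. Records missing a required field
are labeled `UNCLASSIFIED` and counted rather than dropped silently.
Group summaries are computed over the *predicted* biological groups, with
known controls kept as their own reference column. In simulate mode the
bundle is fully deterministic under the configured seed; the manifest
deliberately carries no timestamps.

## Problem sizes and limitations

The shipped tests run the generator at n = 10,000 per group for
calibration checks (3-standard-error tolerance), 100 seeded replicates of
the 154-patient cohort for omnibus power, exhaustive enumeration for the
rank-test oracles up to total n = 8, and all 512 (plus 10,000 random)
feature vectors against a brute-force Hamming minimizer — sizes chosen so
the whole suite completes in well under a minute while leaving Monte-Carlo
margins comfortable.

Known limitations: within-group independence of the generated variables
(above); the classifier's cuts are choices, not estimated quantities, so
downstream accuracy statements are properties of a configuration; the
label-recovery property (≥ 90% on a well-separated cohort, SDs scaled
tenfold down) characterizes rule consistency, not expected performance at
the published, heavily overlapping group SDs; and the feature matcher has
no MI column — infarct detection is the dichotomy's override, mirroring
the source's treatment of MI as a separate category.
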