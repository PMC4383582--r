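---
title: "A hard-margin SVM decision-score biomarker for gray-matter morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hard-margin SVM decision-score biomarker for gray-matter morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmsvm)
```

## The analysis in one paragraph

vbmsvm implements a pattern-classification pipeline for case-control studies
of modulated gray-matter (GM) volume maps, of the kind used to ask whether
preterm birth leaves a recognizable signature in adolescent brain structure.
Each subject contributes one 3D map in a common space. The maps are smoothed,
restricted to a GM mask, and flattened into a subjects-by-voxels feature
matrix on which a *linear hard-margin support vector machine* is trained with
case = +1 and control = -1. The per-subject biomarker is the *decision
score* `f(x) = w . x + b`, the signed distance to the decision boundary:
positive is case-like, negative control-like. Classification performance is
estimated by leave-one-out (LOO) and split-half validation; statistical
significance by label permutation, both globally (accuracy, AUC) and
voxelwise (the weight map); the biomarker is benchmarked against the obvious
global confound, total intracranial volume (TIV), with the DeLong test for
correlated ROC curves; and the scores are correlated with gestational age
(GA), birth weight (BW) and IQ, with WHO GA-band and SGA-excluded
sensitivity analyses.

## The classifier

With many more voxels than subjects (p >> n), the SVM is solved in the dual
over the n-by-n Gram matrix `K = X X'`:

  min 1/2 a'Qa - 1'a,  Q = (y y') * K,  y'a = 0,  0 <= a <= C,

from which `w = sum_i a_i y_i x_i` and the bias `b` follow. "Hard margin" is
realized as `C_effective = 1e8` plus an explicit separability certificate:
after the solve, any dual coefficient at the bound whose margin is violated
beyond `kkt_tol = 1e-4` raises a "not separable" error naming the subjects,
rather than silently absorbing slack. With smoothed GM features and p >> n
the data are separable in practice, so the certificate normally passes; the
two deliberate exceptions are

* the **TIV-only rival classifier**, a single-feature machine that is almost
  never separable and therefore always runs in a flagged margin-tolerant
  mode with a moderate `C = 1`, and
* the **covariate-adjusted reruns**, because residualization projects the
  subject vectors into a space of rank `n - k - 1`, where n points need not
  be separable; these run margin-tolerant and are flagged in the report.

### Two solvers, one contract

The production path is a sequential-minimal-optimization (SMO) solver in C++
with second-order working-set selection. Its stopping rule bounds the
maximal KKT violation in decision-value units (`eps`, default 1e-6 for
training). On nearly-degenerate problems -- above all label-permuted cohorts
of heavily smoothed maps, where the separating margin is tiny and the dual
coefficients huge -- SMO can need millions of iterations, so every fit runs
under an iteration budget (2e5) and falls back to an exact NNLS-style
active-set solver: stationarity on the free set is solved as a dense saddle
system, candidate steps are clipped back to the feasible box
(Lawson-Hanson), and the worst KKT violator is admitted until none remains.
The fallback is insensitive to conditioning and agrees with an independent
quadratic-programming solve of the primal to ~1e-9; the test suite enforces
the solver *contract* (KKT conditions, dual-primal consistency, oracle
agreement) rather than an algorithm.

Tie-break convention: a subject with decision score exactly 0 is predicted
control (-1); documented, arbitrary, and only relevant on degenerate inputs.

### Leave-one-out and its shortcut

For each subject, the model is retrained on the remaining n-1 and the
held-out score recorded. Removing a non-support vector leaves a hard-margin
solution unchanged, so subjects that are not support vectors of the
full-sample model (with margin strictly above `1 + kkt_tol`) inherit the
full-model score without retraining. The shortcut is validated against the
naive loop at 1e-6; refitted folds warm-start the active-set solver from the
full-sample solution. When covariates are removed fold-wise the shortcut is
disabled (the projection differs per fold).

### Covariate removal

Covariates (age at scan, sex, optionally TIV, always with intercept) are
removed by the residual-forming projection `R = I - X (X'X)^- X'`, using the
pseudo-inverse with a warning when the design is rank-deficient. Two modes
exist because whole-sample residualization leaks held-out information into
CV folds: `"foldwise"` (default; the projection is estimated on each fold's
training rows and applied to all rows) and `"paper"` (estimated once on
everyone, as a whole-sample analysis would). Both are reported explicitly.

## Inference

**Permutation tests.** Group labels are permuted uniformly; covariates
travel with their subjects, so the question tested is whether group
assignment is informative given the images. The p-value convention is
`(1 + #{null >= observed}) / (1 + n_perm)` -- never zero, and the smallest
reportable value with N permutations is `1/(N+1)` (with 50,000 permutations,
1/50001, matching a "p < 0.00002" bound style). Default counts are
desk-scale (999 global, 199 voxelwise); study-scale counts (50,000 / 2,000)
are a CLI flag away. Within the permutation loops the solver tolerance is
relaxed to 1e-3: accuracy and AUC depend on scores only at a far coarser
resolution, and permuted-label fits are precisely the ones that are
expensive to polish.

**The voxelwise map** compares *relative* weight magnitudes
`|w_v| / ||w||`, two-sided, because the overall scale of a hard-margin
weight vector is the inverse margin, which explodes under permuted labels;
raw `|w|` comparisons would be dominated by that scale rather than by where
the discriminative load sits. The map is uncorrected for multiple
comparisons, as presented; a max-statistic correction would be a natural
extension.

**DeLong test.** The image-score and TIV-score ROC curves are computed on
the same subjects, so their AUCs are compared with the DeLong
structural-components estimator of the covariance of paired AUCs, a
two-sided normal test on the difference. Per-AUC Wald confidence intervals
(default 95%) are truncated to [0, 1]. Identical scores give a flagged
degenerate variance with p = 1, not a division by zero. AUC itself is the
Mann-Whitney pairwise statistic with midrank tie handling; the ROC sweep
treats tied scores as one threshold.

**Correlations.** Pearson r with two-sided t-transform p-values; missing IQ
handled pairwise with per-row n. Partial correlations residualize both
variables on the covariate design and adjust the degrees of freedom to
`n - 2 - k`.

**WHO stratification** uses the printed half-open bands on gestational age:
extremely preterm GA < 28 w (+3), very preterm 28 <= GA < 32 (+2),
moderately preterm 32 <= GA < 37 (+1), term = controls (-1); a case with
GA >= 37 is a consistency error. Pairwise subgroup classifications relabel
the more-preterm set +1 and rerun the full LOO machinery on the selected
rows.

## The synthetic cohort generator

No MRI data accompany the study this package re-implements, so the generator
is a first-class module whose defaults state the emulated design rather than
a tunable fixture:

* **Design shape.** 74 cases / 69 controls; case GA spanning 24-36 completed
  weeks, control GA 37-42; case BW capped at 1500 g (the inclusion
  criterion); ~22% of cases SGA; age at scan ~14.6 +/- 1.3 y.
* **Latent severity.** Cases carry a severity s ~ Beta(2.8, 1.9) on [0, 1]
  (controls s = 0). The parameters were fixed once by matching the study's
  WHO band proportions (11/36/27 of 74) and case GA mean (28.54 w; the
  generator's analytic mean is 28.85 w) under the linear link
  GA = 36 - 12 s. GA is stored continuously (used for WHO banding) alongside
  a floored completed-weeks column.
* **Images.** Each volume is `scale_i * (template + s_i * effect_map)` plus
  smoothed Gaussian noise, clipped at zero, on a 16^3 grid of 1.5 mm voxels
  with an ellipsoidal "brain" (~2,000 masked voxels, preserving p >> n at
  desk scale). The effect map is a sum of signed spheres -- two positive,
  two negative, mirroring a bidirectional discriminative pattern. The
  default amplitude (0.06) was calibrated once so that an oracle readout
  along the true effect direction classifies a large cohort at ~95%
  accuracy, and was not revisited afterwards.
* **TIV confound.** The per-subject global scale is the true TIV driver:
  reduced by 5% on average in cases, ~4% larger in boys, declining ~1%/year
  with age, with 6% lognormal within-group spread. Setting both `tiv_sd` and
  `tiv_group_gap` to zero disables this machinery entirely, leaving a pure
  voxel-noise null cohort (used by the calibration tests, where a shared
  global factor would make voxelwise statistics degenerate by construction).
* **Clinical links.** BW rises linearly with GA (cases ~800 g at 24 w to
  ~1400 g at 36 w, residual sd 150 g; controls ~2800-4200 g, sd 350 g); SGA
  cases are chosen independently of severity and have their BW-given-GA
  residual redrawn from the lowest decile, so SGA subjects span the severity
  range. IQ = 100 - 12 s plus noise (sd ~11), with verbal/performance
  variants at 0.9/0.8 of the slope and ~15% of subjects missing IQ.
* **Modulation is emulated, not implemented.** Segmentation, nonlinear
  registration and Jacobian modulation are out of scope; the global scale
  factor stands in for modulation, and TIV is computed from the GM map total
  (the only tissue map that exists in this world) -- a documented divergence
  from real data, where TIV would sum all tissue segments.

What a green test on this world does establish: the pipeline's estimators
and tests are correct, calibrated, and recover planted structure (orderings,
signs, subgroup gradients) at realistic n and p >> n geometry. What it does
not establish: the study's actual effect sizes or accuracies, realistic
neuroanatomy, scanner artifacts, registration error, or tissue-class
cross-talk. Headline numbers from the study (93% LOO accuracy, AUC 0.9755,
subgroup means 0.43/0.73/1.20, ...) are therefore treated as *structural*
targets -- reproduced in kind, not in value.

## Numerical choices

* SMO duality-gap tolerance 1e-6 (training), 1e-3 (permutation loops);
  iteration budget 2e5 before the exact active-set fallback.
* KKT margin tolerance 1e-4; support vectors are `alpha > 1e-6 * max(alpha)`.
* Active-set solves use a 1e-10-scaled ridge on the saddle system and an
  SVD pseudo-inverse if the factorization still fails; bound tolerances
  scale with the solution, never with the (huge) C.
* Smoothing uses a normalized discrete Gaussian truncated at 4 sigma with
  `sigma_vox = fwhm / (voxel_size * 2 sqrt(2 ln 2))`; the default boundary
  rule is zero padding (mass crossing the grid edge is lost), with
  `"nearest"` replication as an option. FWHM 0 is the identity.
* The mask threshold (0.1, in the maps' arbitrary GM units) is applied to
  the across-subject mean; an empty mask is an error advising a lower
  threshold.
* NIfTI-1 I/O is a minimal purpose-built reader/writer (no NIfTI package
  exists in the supported dependency set), handling both byte orders, the
  common datatypes, scl slope/intercept and the sform affine; files written
  here are read back bit-consistently by nibabel and vice versa at storage
  precision (float32 by default).
* Degenerate inputs are surfaced, not patched: one-class training data,
  constant TIV, zero-variance correlation inputs, empty masks and empty
  subgroups all raise or flag explicitly.

## Known limitations

* The voxel p map is uncorrected; no family-wise or FDR control.
* The split-half scheme follows the study (two cycles of a fixed-size random
  split); it is a validity check, not a variance estimate.
* Whether the original analysis refit its covariate projection per LOO fold
  is not stated in the source; both modes are provided and labelled, with
  the leakage-safe fold-wise mode as default.
* The LOO estimate of null-model accuracy is slightly anti-conservative in
  a specific sense: on balanced data with no signal, a majority-tracking
  classifier scores *below* 0.5 because the held-out subject's class is
  always the training minority. This is a property of LOO itself and is
  visible in the TIV-only null, not a defect of the permutation test (which
  compares like with like).
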