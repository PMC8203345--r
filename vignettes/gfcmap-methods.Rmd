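---
title: "Global-brain functional connectivity mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-brain functional connectivity mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfcmap)
```

## The statistic and the study design

Global-brain functional connectivity (GFC, also called global brain
connectivity or GBC) summarises, per voxel, how strongly that voxel's
resting-state BOLD time series covaries with the rest of gray matter:

$$\mathrm{GFC}_i \;=\; \operatorname{arctanh}\!\Big(\tfrac{1}{V-1}\sum_{j \ne i} r_{ij}\Big),$$

where $r_{ij}$ is the Pearson correlation between the series of voxels
$i$ and $j$, both inside a gray-matter mask of $V$ voxels obtained by
strict thresholding of a gray-matter probability map (probability
strictly greater than 0.2 by default, the conventional SPM cutoff).
Correlations enter the average **in signed form** — negative
correlations are not discarded or rectified — and the self-correlation
is excluded. The Fisher transform `arctanh` is applied to improve
normality before group statistics.

`gfcmap` implements the full downstream design around that statistic:
frame-wise-displacement motion QC with whole-subject exclusion,
voxel-wise covariate-adjusted two-sample inference with family-wise
error (FWE) control, cluster extraction with peak MNI coordinates,
Pearson screening of cluster-mean GFC against clinical variables with
Bonferroni control, and single-region leave-one-out cross-validated
(LOOCV) RBF-SVM classification of patients versus controls. A
synthetic-cohort generator provides a fully specified study — volumes,
masks, motion, clinical table and ground truth — so every stage is
testable end to end.

## Order of the Fisher transform

The phrase "mean correlation, Fisher transformed" is ambiguous between
$\operatorname{arctanh}(\bar r)$ and
$\overline{\operatorname{arctanh}(r)}$. The package's default is
`z_of_mean_r` (transform the mean), which matches the order in which the
quantities are usually described and admits an exact $O(VT)$
reformulation: with each masked series standardised to zero mean and
unit $L_2$ norm ($u_i$), row sums of the correlation matrix are
$u_i \cdot S$ with $S = \sum_j u_j$, so the self-excluded mean is
$(u_i \cdot S - 1)/(V-1)$. The alternative `mean_of_z` is available
behind a flag and computed in voxel blocks to bound memory at
$O(\text{block} \times V)$. The two agree to first order whenever all
$|r_{ij}|$ are small (the package tests $\le 0.01$ map difference when
$|r_{ij}| \lesssim 0.1$); the choice is recorded in every map's
metadata and JSON sidecar. Correlations are clamped to
$\pm(1 - 10^{-7})$ before `arctanh` so degenerate perfect correlations
stay finite and NIfTI-storable.

## Motion quality control

Frame-wise displacement is the Power-style backward difference
$\mathrm{FD}_t = \sum |\Delta \text{trans}| + 50\,\mathrm{mm}
\cdot \sum |\Delta \text{rot}|$ with rotations in radians converted to
arc length on a 50 mm sphere; the first frame's FD is 0 by definition.
Subjects are excluded — whole subjects, never individual frames — when
mean FD exceeds 0.2 mm or any absolute translation exceeds 2 mm or any
rotation exceeds 2°. No numeric criterion is canonical for this design;
these defaults follow common resting-state practice and are all
configurable, and the QC log records which criterion each excluded
subject violated. Each retained subject's mean FD then enters the
group model as a nuisance covariate.

## Group inference

Each voxel's Fisher-z GFC is regressed on an intercept, the group
indicator (patients = 1) and centered nuisance covariates (age, sex,
years of education, mean FD); the reported t tests the group column
with $n - p$ degrees of freedom, reducing exactly to the pooled
two-sample t when no covariates are supplied. Voxels with zero residual
variance and zero contrast estimate are assigned $t = 0$ rather than
0/0.

FWE control defaults to a **max-T permutation test with Freedman–Lane
nuisance handling**: nuisance-only residuals are permuted over
subjects, each permuted response is refit against the full design, and
the maximum $|t|$ over the mask is recorded; the corrected threshold is
the empirical $(1-\alpha)$ quantile (type-1, so $\alpha = 1 - 1/B$
recovers the null minimum) and voxels strictly above it are
significant. This is preferred over Gaussian-random-field corrections
because it is essentially exact at toy grid sizes without smoothness
estimation; Bonferroni ($\alpha / V$ per voxel) is offered as a fast
fallback. The permutation loop uses an algebraically equivalent
low-rank form (each permutation is one tall-thin matrix product), which
the test suite verifies against an explicit refit to $10^{-9}$.

Significant voxels are partitioned into 26-connected components
(6/18 available), separately per sign of t so opposite-direction
clusters never merge; each cluster reports voxel count, peak $|t|$
(ties broken by mask order) and the peak's MNI coordinate via the NIfTI
affine. No cluster-extent threshold is applied: voxel-level correction
alone defines significance.

## Clinical correlations and classification

Cluster-mean Fisher-z values are screened against clinical variables by
Pearson correlation among patients only (clinical scales and lipid
panels are collected for patients), with pairwise deletion of missing
values and never imputation. The Bonferroni threshold divides
$\alpha = 0.05$ by the number of tests actually performed; the family
is all cluster-by-variable pairs by default, with a per-cluster option,
and both the uncorrected p and the applied threshold are always
reported so either multiplicity convention can be reproduced from the
output. Shapiro–Wilk normality of the cluster means is reported but
never used as a gate.

The classifier is an RBF-kernel SVM on a single region's cluster-mean
GFC with leave-one-out cross-validation. By default the hyperparameters
($C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{0.01, 0.1, 1, 10\}$) are
chosen per outer fold by an **inner** leave-one-out grid search on the
training subjects (ties broken by fixed grid order), and features are
standardised with training-fold statistics only, so the reported
sensitivity/specificity/accuracy carry no selection leakage from the
held-out subject. The non-nested variant — tuning on the same loop that
is reported, which is the historically common but optimistic protocol —
is available behind `nested = FALSE` and flags its report accordingly.
Because the classified region is itself selected by a group contrast on
the same subjects, every report also carries a selection-circularity
warning; the package reproduces that design rather than silently
correcting it.

## The synthetic cohort: what it emulates and what it does not

`cohortSpec()` defaults define the package's reference study, sized so
a full end-to-end run takes seconds: 38 patients and 40 controls on a
$16^3$ grid (3 mm isotropic, MNI-like origin), 150 frames at TR 2 s, a
central gray-matter blob covering 25% of the grid (1024 voxels), and a
spherical "hub" of radius 3 voxels (123 voxels) centred in gray matter.
Each subject's volume is spatially smoothed white noise (Gaussian,
FWHM 2 voxels — so the permutation machinery faces realistic spatial
autocorrelation rather than trivially independent voxels) plus a
subject-specific standard-normal latent time series added to hub voxels
only, weighted by a coupling drawn from
$\mathcal{N}(\mu_g, 0.25)$ truncated at zero, with $\mu = 0.8$ for
patients and $0.25$ for controls. The smoothing kernel rows are
normalised to unit $L_2$ norm, so `noiseSD` is the standard deviation
of the *smoothed* field and coupling weights are interpretable relative
to it. Three subjects per group receive a 3 mm mid-scan position shift
plus elevated jitter, so the default QC retains exactly 35 + 37 — the
reference sample sizes. Patient clinical variables are built as
$x = \rho\,\tilde c + \sqrt{1-\rho^2}\,\varepsilon$ from the
standardised true coupling $\tilde c$, then rescaled to plausible
clinical units (e.g. TG $1.06 \pm 0.92$ mmol/L); default planted
correlations are TG 0.45, LDL-C 0.42, RBANS coding −0.40, Stroop color
−0.47, with five null variables alongside.

Two generator behaviours deserve emphasis because they shaped the
defaults:

* **Hub GFC is non-monotone in coupling.** Adding an unsmoothed latent
  signal to hub voxels strengthens hub–hub correlations but *attenuates*
  the hub voxels' smoothing-induced correlations with their non-hub
  neighbours (the latent acts as uncorrelated variance in those pairs).
  The hub-mean GFC therefore rises, plateaus and can even fall as
  coupling grows. The default couplings (0.8 vs 0.25 relative to
  unit-variance noise) sit on the rising limb with a gap large enough
  that the planted hub is recovered with Dice ≥ 0.94 across validation
  seeds; the resulting peak t (roughly 6–10 at $n = 72$) is
  deliberately on the generous side of what a comparable clinical
  study reports, because recovery reliability was prioritised over
  matching any particular printed t.
* **Measured clinical correlations are attenuated.** The planted
  correlation is with the *true* coupling; what the pipeline measures
  is the correlation with the *extracted cluster-mean GFC*, which adds
  GFC estimation noise (finite frames, latent-versus-noise chance
  correlations). With the default between-patient coupling SD of 0.25
  this attenuates the measurable correlation to roughly 0.75 of the
  planted value — a genuine property of two-stage designs, not a bug.
  The correlation-recovery validation therefore uses a cohort with a
  wider coupling spread and a correspondingly wider group gap (means
  1.1 vs 0.15, SD 0.5 — the gap compensates for the variance the spread
  adds to the group comparison, and for the fact that truncation at
  zero raises the realised control mean), where hub-GFC variation is
  coupling-dominated and the planted r = 0.45 at n = 35 is recovered
  within its Fisher-z 95% CI in 19 of 20 validation seeds.

The generator does **not** emulate hemodynamic response shapes,
physiological (cardiac/respiratory) noise, multi-site effects, or more
than one latent network. Passing tests on this cohort therefore
demonstrate the *statistical machinery* — FWE calibration, recovery,
determinism — not robustness to the full noise structure of real fMRI.

## Numerical choices and degenerate inputs

* Mask ordering is fixed (first grid axis fastest) so value vectors are
  reproducibly indexed; NIfTI affines apply to 0-based voxel indices.
* Zero-variance mask voxels are an error from `computeGFC()` (they have
  no defined correlation); `dropConstantVoxels()` shrinks the mask
  explicitly, with the removal count reported — nothing is dropped
  silently.
* Optional preprocessing (off by default, for already-clean inputs)
  applies per-voxel linear detrend, then least-squares removal of the
  six motion regressors, then a discrete-Fourier band-pass keeping bins
  with $f_\text{low} \le f \le f_\text{high}$; the order is fixed and
  the high edge must be below Nyquist.
* All randomness flows from explicit integer seeds; the pipeline fans a
  single global seed out to per-stage seeds by a fixed string-hash
  derivation, so stages are independently reproducible and identical
  configs give byte-identical outputs on one platform.
* Motion files are read as SPM-convention radians; degree input exists
  only behind an explicit flag — units are never guessed.

## Problem sizes used by the validation suite

The test suite runs the full pipeline at the reference size
(78 subjects before QC, $16^3$ grid, 1024-voxel mask, 150 frames,
1000 permutations): 40 seeds under the global null for FWE calibration,
20 seeds for hub recovery, 20 seeds for correlation recovery, and 200
label permutations for the classifier's chance-level check, alongside
brute-force oracle comparisons on grids up to $6^3 \times 60$. These
sizes were chosen as the smallest at which the calibration statements
are statistically meaningful.

## Known limitations

* The GFC fast path requires the full masked series in memory
  (voxels × frames doubles per subject); realistic whole-brain grids
  fit comfortably, but the package streams subjects rather than
  holding a cohort of 4D volumes at once.
* Permutation FWE assumes exchangeability of nuisance-adjusted
  residuals across subjects; grossly heteroscedastic groups would need
  a studentised variant that is not implemented.
* Surface-based (CIFTI) input, sliding-window connectivity, seed/ROI
  matrices, cluster-mass or TFCE statistics, partial correlations and
  Spearman variants are out of scope.
* The single-region classifier inherits the selection circularity of
  the design it reproduces; its rates should be read as descriptive,
  not as out-of-sample performance.
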