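---
title: "Diffusion-based parcellation of the hypothalamus: methods and design"
author: "hypoparc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-based parcellation of the hypothalamus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The hypothalamus is a small (~1 cm^3 per hemisphere) grey-matter structure
composed of functionally distinct nuclei, too small and too poorly contrasted
for reliable T1-based subdivision. Its local diffusion profile, however,
carries structure: different compartments have different dominant fiber
orientations and different amounts of traversing white matter. `hypoparc`
parcellates a hypothalamus mask from single-shell diffusion-weighted MRI
(DWI) into four subunits — anterior-superior, anterior-inferior,
intermediate, posterior — by clustering voxels on their position *and* their
diffusion orientation distribution function (ODF), then relates subunit
microstructure (mean diffusivity, MD) to body-mass index across a cohort.

# The pipeline

For one subject, `runSubject()` executes:

1. **Shell extraction** (`extractShell`): keep the b = 1000 s/mm^2 shell plus
   all b = 0 volumes from a multi-shell acquisition.
2. **Tensor fit** (`fitTensor`): per-voxel weighted-least-squares log-linear
   fit; FA and MD maps. FA is
   `sqrt(1/2) * sqrt(sum_{i<j} (l_i - l_j)^2) / sqrt(sum_i l_i^2)` over the
   eigenvalues; MD their mean.
3. **Mask refinement** (`refineMask`): voxels with CSF probability > 0.15
   (partial-volume contamination from the third ventricle) or FA > 0.55
   (fornix, optic tract) are excluded. Thresholds are inclusive-keep,
   matching the "strictly greater than" exclusion wording they implement.
4. **CSA ODF estimation** (`fitCsaOdf`): constant-solid-angle q-ball. The
   attenuation E = S/S0 is clipped into (1e-4, 1 - 1e-4); the double-log
   transform ln(-ln E) is expanded in a real, symmetric, even-order
   spherical-harmonic (SH) basis up to lmax = 6 (28 coefficients) with
   Laplace-Beltrami regularization (weight 0.006); the Funk-Radon transform
   and sharpening yield the ODF in SH coefficients,
   `psi = 1/(4 pi) + 1/(16 pi^2) FRT(Laplacian_b ln(-ln E))`, i.e. order-l
   coefficients scale by `-l(l+1) P_l(0) / (8 pi)` and the l = 0 coefficient
   is the unit-mass constant `1/(2 sqrt(pi))`. Optionally
   (`bootstrapOdf`) the SH regression is residual-bootstrapped (50
   replicates) and the mean coefficient vector returned.
5. **Feature construction** (`buildFeatures`): one row per in-mask voxel,
   [world x, y, z in mm | 28 SH coefficients], every column standardized to
   mean 0 / SD 1. Standardization removes voxel-size and coefficient-scale
   effects; the constant l = 0 column is zeroed.
6. **Clustering** (`initCentroids`, `weightedKmeans`, `selectK`): k-means
   under the block-weighted metric
   `d(v, c)^2 = 0.5 ||p_v - p_c||^2 + 0.5 ||o_v - o_c||^2`.
   The weights act on the squared block distances, which keeps the blockwise
   mean the optimal centroid update (equivalently each standardized block is
   scaled by sqrt(0.5)). Initialization follows the position-averaging
   scheme: many (default 5000) spatial-only k-means runs, centroids of every
   run matched to run 1 by minimum-cost permutation (exhaustive, k <= 6) and
   averaged; the ODF block of an initial centroid is the mean ODF feature of
   the voxels nearest its spatial centroid. The number of clusters is chosen
   by minimizing the Davies-Bouldin index over k = 2..6 (ties toward smaller
   k).
7. **Anatomical labelling** (`labelClustersAnatomically`): with k = 4, the
   most posterior centroid (smallest y) is `posterior`, the next
   `intermediate`, and the remaining two split by z into `anterior-superior`
   and `anterior-inferior`. Any deciding coordinate difference below 0.5 mm
   makes the subject `unclassifiable`, mirroring the small fraction of real
   subjects whose cluster layout does not fit the scheme.

At the cohort level (`runCohort`): aligned per-subject label maps are fused
by majority voting (`buildProbabilisticAtlas`) into per-label count volumes
plus a max-count label map; per-subject, per-subunit Dice coefficients
against the atlas quantify consistency; subunit volume (ICV-corrected by the
residual approach), FA and MD are compared with three one-way ANOVAs (Tukey
HSD, alpha = 0.017 after Bonferroni adjustment for the three tests); and BMI
is regressed on the four subunit MDs, cardiovascular fitness, age and sex
(`fitBmiModel`), with per-predictor variance inflation factors.

# Tunable parameters

| parameter | default | unit | notes |
|---|---|---|---|
| `b_target`, `b_tol` | 1000, 100 | s/mm^2 | shell selection window |
| `lmax` | 6 | — | 28 SH coefficients; needs >= 28 directions |
| `reg_lambda` | 0.006 | — | Laplace-Beltrami weight, the standard CSA value |
| `clip_eps` | 1e-4 | — | keeps ln(-ln E) finite at extreme attenuations |
| `csf_thresh` | 0.15 | probability | CSF exclusion |
| `fa_thresh` | 0.55 | — | white-matter exclusion |
| `w_spatial`, `w_odf` | 0.5, 0.5 | — | block weights on squared distances |
| `n_init_runs` | 5000 | — | position-only initialization runs |
| `k_range` | 2..6 | — | Davies-Bouldin candidates |
| `n_samples` | 50 | — | residual-bootstrap replicates (optional path) |

The deterministic SH fit is the default clustering input; bootstrap
averaging is available but changes coefficients only marginally (its mean
equals the deterministic fit exactly when residuals vanish). All randomness
(gradient rotation, initialization, noise, cohort generation) is governed by
explicit integer seeds, and a full `runSubject()` is byte-reproducible from
its config.

# The synthetic phantom: what it emulates and why it looks the way it does

`defaultPhantomSpec()` generates the ground-truth world for validation: a
~0.7 cm^3 blob of 1.25 mm isotropic voxels formed by four overlapping
spherical lobes (radius 2.9 voxels) with a one-voxel isotropic CSF rim
(3.0e-3 mm^2/s), imaged with ~90 uniformly spread directions at b = 1000
plus 6 interspersed b = 0 volumes and Rician noise at SNR 20 — a typical
single-shell regime.

Two design choices deserve explanation because naive alternatives fail in
instructive ways:

* **Lobe geometry instead of a partitioned ellipsoid.** Voxel coordinates
  are standardized per axis before clustering, which maps any convex blob
  onto a near-sphere: a partitioned ellipsoid therefore gives the
  position-only initialization no spatial structure to lock onto — its
  averaged centroids blur over rotationally equivalent k-means optima, and a
  symmetric anterior split becomes a stable mixed local optimum. Four
  compact lobes separated by density valleys make the spatial 4-means
  solution essentially unique. The lobe centres are spread along *all three*
  axes (the anatomical y/z layout plus alternating x offsets); otherwise the
  axis without between-lobe spread is stretched by standardization into a
  pure within-lobe direction that spatial k-means then splits.
* **Crossing-fiber signatures instead of single tensors.** Each subunit
  carries two orthogonal prolate "stick" compartments (eigenvalues
  (1.5, 0.25, 0.25)e-3 mm^2/s, 50/50). The crossing keeps the voxel-average
  tensor oblate with FA ~ 0.50 — below the 0.55 refinement threshold, as in
  real hypothalamic tissue with traversing fibers — while the ODF retains
  strong angular contrast, roughly twice what a threshold-respecting single
  tensor could offer. Orientation pairs of distinct subunits differ by at
  least 45 degrees, and the four signatures are chosen approximately
  equidistant in SH coefficient space (three rotated coordinate-plane
  crossings plus the axis-aligned pair), with the two closest signatures
  assigned to the two most spatially distant lobes: an ODF-outlier subunit
  would otherwise make "split that one off" a competitive 2-cluster
  solution under the Davies-Bouldin criterion.

The cohort generator (`makeCohort`) adds per-subject variation: the
anterior-superior eigenvalues scale with a standardized latent `z_md`
(8% coefficient of variation on MD; 4% independently elsewhere), each lobe
centre jitters by one voxel along one random axis (geometry drawn again in
the rare case a region is pinched apart), and covariates are generated as
BMI = 26.5 + 4.2 (beta_md z_md + beta_fitness z_fit) + e. When `noise_sd`
is unspecified it is completed so that the standardized BMI variance is 1,
making the population standardized coefficient of anterior-superior MD
exactly `beta_md` — the property the parameter-recovery tests check.
Defaults beta_md = 0.3 and beta_fitness = -0.29 reproduce the magnitude of
the reported subunit-MD and fitness associations; sex is Bernoulli(0.5) and
age uniform 22-36, both with zero true effect.

**What passing tests do and do not show.** The phantom establishes that the
implementation recovers planted structure under magnitude noise at realistic
SNR: correct ODF peaks, exact tensor quantities, Dice ~ 1 at k = 4, correct
model selection, unbiased effect recovery. Real data differ in ways the
phantom does not model: partial-volume mixtures at boundaries, spatially
varying SNR, imperfect masks and registration, inter-subject anatomical
variability far richer than one-voxel jitter, and subunit contrasts much
weaker than the designed signatures. Phantom results are therefore evidence
of implementation correctness, not of clinical performance.

# Numerical choices and degenerate inputs

* Attenuations are clipped to (1e-4, 1 - 1e-4) before the double-log; all-zero
  voxels are flagged and set to the isotropic ODF.
* Non-positive signals entering the tensor log-fit are clipped to a small
  positive floor and counted in a message.
* Constant feature columns (SD = 0) are zeroed rather than divided by zero.
* Empty clusters during Lloyd iterations are re-seeded at the farthest point
  (logged); the objective trace is retained in the result.
* Davies-Bouldin ties in `selectK` break toward smaller k; atlas count ties
  break toward the smaller label id; background wins atlas votes on ties, so
  fringe voxels covered by a minority of subjects stay background.
* Dice of two empty masks is defined as 1 (logged).
* `icc31` refuses constant ratings (the coefficient is undefined); its
  confidence interval is the exact F-based interval of the single-score
  formulation.
* The ICV residual correction is mean-preserving: the fitted slope is removed
  around the ICV mean.
* In the BMI model, continuous response and predictors are z-scored (so
  coefficients are standardized) while the sex indicator stays a raw 0/1
  (`sex_male`); its coefficient is therefore on a different scale, consistent
  with reporting conventions for binary covariates. Rank-deficient designs
  abort with the collinear columns named.

# Problem sizes used by the test-suite and acceptance script

Simulated experiments use the default phantom (~390 in-mask voxels, 96
volumes), 10 noise realizations for clustering recovery and model selection,
300 initialization runs per k (the full 5000 of the interactive default adds
stability on real data but none on the phantom), cohorts of 20 subjects for
atlas fusion and of 100 subjects x 20 replicates for regression recovery.

# Known limitations

* Registration to a common space is out of scope; the atlas builder assumes
  label maps already share a grid.
* No multi-shell ODF models, no peak extraction, no tractography.
* Anatomical labelling is defined for k = 4 only, by design.
* The 4-lobe phantom is a correctness instrument; it does not emulate
  partial-volume effects or realistic inter-subject registration error.
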