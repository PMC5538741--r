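---
title: "Quantifying three aetiologies of brain injury from structural MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying three aetiologies of brain injury from structural MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Children with unilateral cerebral palsy carry brain injury that radiologists
classify into three aetiologies: cortical malformations (shape abnormality of
the cortical ribbon), white and grey matter lesions (focal intensity
abnormality), and ventricular enlargement (secondary to periventricular
tissue loss). Routine structural MRI shows these injuries but they are mostly
assessed qualitatively. `cpinjury` implements an automated pipeline that
turns a T1/T2 pair into quantitative regional biomarkers of the three injury
classes, applies binary injury-presence rules, and relates the biomarkers to
clinical scores of motor, cognitive, visual and communicative function
through negativity-constrained sparse regression.

Because the pipeline's validation requires ground truth that no clinical
dataset provides, the package ships a first-class synthetic phantom
generator: every stage is exercised on 3D brain phantoms whose tissue
labels, lesion volumes, enlargement volumes and ribbon thicknesses are known
exactly.

## The phantom generator

`build_anatomy()` constructs a sulcated ellipsoid shell: background, a skull
shell, an intradural CSF layer, a cortical grey-matter ribbon of constant
thickness, white matter, two ellipsoidal lateral ventricles, and a deep grey
matter shell around each ventricle. The pial surface is an ellipsoid whose
normalized radius is perturbed by a separable cosine field (the "sulci"),
chosen to be mirror-symmetric so hemisphere label counts agree exactly. The
atlas partitions the ribbon into 8 angular sectors, white matter into 4
quadrants, and the deep grey shell into 4 anatomies (left/right x
anterior/posterior); ids are stable across subjects because all phantoms
share one spatial frame.

Injuries (`inject_injuries()`):

* **lesions** — spheres relabelled inside their host tissue, with a
  multiplicative intensity contrast per modality. The defaults make lesions
  T2-hyperintense and distinct from every healthy class (WM lesions
  T1 x 0.85 / T2 x 1.9; GM lesions T1 x 0.8 / T2 x 1.3): lesions whose
  intensity collapses onto another tissue are unidentifiable by any
  intensity model, a case the tests cover separately.
* **ventricular enlargement** — the ventricle mask grows outward through
  white and deep grey matter in distance-ordered layers, the final partial
  layer filled preferentially along the requested direction, so the added
  volume is met to within one voxel.
* **cortical thinning** — the outer part of a named sector's ribbon is
  relabelled to CSF. The cut depth is feathered with a smoothstep taper
  starting 4 mm inside the sector (full depth from 12 mm): thinning in one
  region then leaves no measurable cliff in its neighbours' shape measures,
  which mirrors how real atrophy blends into surrounding cortex.

`simulate_mri()` assigns per-tissue mean intensities, multiplies by a smooth
random polynomial bias field (order 2, peak amplitude 15% by default) and
applies Rician corruption `sqrt((s + n1)^2 + n2^2)`, the magnitude-MRI noise
model. The default noise (sigma 4.5 on a WM intensity of 90) corresponds to
SNR 20; at that ratio the Rician sd matches the Gaussian sigma within a few
percent on flat regions. No partial-volume mixing is simulated — each voxel
is a pure tissue — so segmentation floors quoted below measure the intensity
model, not sub-voxel effects.

`simulate_cohort()` draws per-subject covariates (age Uniform(5, 17) years,
sex Bernoulli(0.5), scanner sequence A/B) and jitters the anatomy between
subjects (brain radii sd 3%, ribbon thickness sd 5%, sulcal amplitude
sd 10%, ventricle radii sd 5%). This jitter is what gives the normative
statistics and the ventricle shape model realistic between-subject spread;
without it control z-scores degenerate. Patients draw injuries from a
sampler whose defaults follow the cohort the pipeline is designed for:
lesions in 55% of patients, cortical thinning in 30%, and enlargement in
75% of lesion carriers versus 60% otherwise — a marginal enlargement rate
near 68% with the lesion-enlargement co-occurrence above 60% that reflects
enlargement being a secondary consequence of periventricular tissue loss.

Clinical scores (`simulate_clinical_scores()`) are sparse linear functions
of *true* injury features — millimetres of ribbon loss per region and mL of
regional lesion load — plus age/sex/sequence effects and Gaussian noise. All
biomarker weights are constrained non-positive (injury can only reduce
function), matching the sign constraint the models later enforce.
Enlargement carries no direct weight: in the generative model it is a
correlated consequence of lesions, so selection should discard it — a
property the tests assert. Thinning weights are a few score points per mm;
lesion weights ~0.5-2 points per mL, chosen so both families carry
comparable signal at the phantom's 0.5-12 mL lesion sizes. When a target
R^2 is requested (default 0.7) the noise sd is calibrated per score from
the realized linear-predictor variance.

## Pre-processing

* `affine_register()` — rigid 6-parameter registration by multi-resolution
  mean-squared-error matching. The translation is initialised from the
  intensity centroid offset, each level is mildly smoothed, and the metric
  is evaluated on a half-voxel-offset grid through which *both* images are
  interpolated. The offset grid matters: when the moving image is itself a
  resampled copy, lattice-aligned candidates otherwise enjoy a spurious
  interpolation-blur advantage that traps the optimiser at the identity.
  Recovery on noise-free phantoms is well under 0.5 mm / 0.5 degrees for
  perturbations up to 10 mm / 10 degrees. The cohort pipeline itself applies
  no registration: all phantoms share one frame, so the atlas is already
  in-register, and the operation is exercised on known perturbations in the
  tests instead.
* `correct_bias()` — a polynomial log-domain surrogate for N4-style
  correction: an order-3 field is fit by iteratively reweighted least
  squares (Cauchy weights, 10 iterations) to the log-intensities of the
  in-mask voxels above the 60th intensity percentile — in practice the
  white-matter compartment. Restricting the fit to one tissue is essential: within one tissue the log residual is
  exactly the log bias, whereas fitting across tissues lets the quadratic
  and cubic terms absorb the brain's radial anatomy and destroy tissue
  contrast (an effect we measured directly: unrestricted order-3 fits cut
  segmentation accuracy from 0.9996 to 0.85).
* `denoise_mcde()` — explicit modified-curvature diffusion,
  `I <- I + dt |grad I| div(c(|grad I|) grad I / |grad I|)` with rational
  conductance `c(g) = 1/(1+(g/kappa)^2)`; kappa defaults to twice the image
  sd and `dt = 0.0625` is the 3D explicit stability bound.
* `normalize_intensity()` — linear rescaling of the in-mask 1st/99th
  percentiles to 0/1.
* `strip_skull()` — Otsu threshold, opening (ball radius 2 voxels), largest
  component, hole filling, closing, then a 2 mm outward dilation so the mask
  covers brain tissue plus intradural CSF while excluding the skull shell.
  Failure (no component covering 1% of the grid) raises an error rather than
  silently editing anything.

## Tissue and lesion segmentation

`fit_em_mrf()` fits a bivariate (T1, T2) Gaussian mixture with spatially
varying priors and a mean-field Potts smoothness term folded into each
E-step (6-neighbourhood, coupling beta = 0.5 by default; mean-field rather
than ICM because downstream stages consume smooth posteriors). The
smoothness term is applied from the second iteration onward — the first pass
is pure prior-times-likelihood, so smoothing cannot lock in the initial
labelling before the data have spoken. Priors come from the template
anatomy as distance-kernel maps (`make_tissue_priors()`, sigma 2.5 mm,
floor 0.01); on phantoms the template plays the role of a registered atlas.
Covariances are ridge-regularised (1e-6 of the trace) when degenerate, which
also covers the noise-free case. At beta = 0 the observed-data log-likelihood
is monotone, and convergence is declared when the mean absolute posterior
change falls below 1e-4.

`detect_lesions()` adds two explicit outlier components — the
lesion-as-outlier idea realised inside the mixture rather than by post-hoc
thresholding. Each lesion class is initialised on the empirical
T2-hyperintense tail of its parent tissue (voxels beyond mean + 3 sd within
the parent's prior support; mean + 2 sd as fallback when no outliers exist)
and receives a small uniform spatial prior (epsilon = 0.03) inside the
parent support. After the 5-class refit, lesion masks are the argmax
voxels; components or connected clumps below 5 voxels dissolve back into
parent tissue, which keeps the control false-positive floor at or below one
voxel layer. Detection requires T2; with T1 only the mixture degrades to
univariate and the lesion stage is skipped (columns propagate as missing).

`regional_lesion_volumes()` converts masks to mL per atlas region — GM
lesions against cortical and deep grey regions, WM lesions against white
matter regions, with an explicit "other" bucket so the per-region volumes
always sum exactly to the total.

## Cortical shape

Three voxel-based measures on the pial surface (`compute_shape_maps()`):

* thickness: distance-to-WM plus distance-to-exterior, minus one voxel for
  the centre-to-centre offset. A symmetric nearest-boundary sum rather than
  Laplacian streamlines: exact on the phantom's constant-width ribbon and
  O(N) via two distance transforms.
* curvature: divergence of the normalised gradient of the signed-distance
  embedding of the pial surface (the sum of principal curvatures, 2/R on a
  sphere, units 1/mm), computed on a twice binomially-smoothed field because
  raw voxelized distance fields have second derivatives dominated by
  lattice noise. A Gaussian-curvature variant (units 1/mm^2, adjugate
  Hessian formula) sits behind `gaussian_curvature = TRUE`; the mean
  curvature is the default reported metric.
* sulcal depth: Euclidean distance below the outer hull (morphological
  closing, ball radius 15 mm — common morphometry practice). The closing
  pads the grid by the ball radius first; clipped dilations at the
  field-of-view border otherwise fabricate several millimetres of spurious
  depth at the poles.

Regional summaries are means over each cortical sector's surface voxels
(sectors with fewer than 20 flagged unreliable); normative statistics
require at least 10 controls; and the biomarker is the absolute z-score
`|x - mu|/sigma`, so all shape biomarkers are non-negative with larger =
more abnormal, aligning them with the volumetric biomarkers and the sign
constraint. Regions whose ribbon is destroyed return flagged missing values
rather than zeros.

## Ventricle shape model

Shape correspondence uses signed-distance fields on a common aligned grid
(no mesh landmarking, hence no correspondence error at phantom scale).
`build_ssm()` is a PCA of the centred fields per side, retaining the
smallest mode count reaching 95% variance, with eigenvector signs fixed for
determinism. `reconstruct_healthy()` projects a patient onto the retained
modes and clamps each coefficient at +-3 sqrt(eigenvalue) — the healthy
variability envelope; the clamp constant is this package's choice of where
"healthy" ends. Enlargement is the region inside the patient ventricle but
outside the reconstruction, each voxel attributed to the nearest deep grey
anatomy so the attribution partitions the total exactly. Left and right are
modelled separately.

A consequence of the healthy-envelope definition worth stating plainly:
enlargement volumes are conservative. The reconstruction may absorb the part
of a bulge that plausible healthy anatomy (a generally larger ventricle)
could explain — at this package's between-subject ventricle variability,
roughly a third to a half of a 2 mL focal bulge. Detected enlargement is
deterministic, monotone in the injected volume, correctly lateralized and
attributed, but it underestimates the injected volume; downstream models
see it as a (scaled) noisy proxy, which is also why its features are the
first to be discarded by selection.

## Structure-function models

Per clinical score: complete cases, a sex-stratified 75/25 split, 10-fold
cross-validation of the penalty over a 100-point log grid spanning
[1e-3 lambda_max, lambda_max], the negativity-constrained LASSO, an
unconstrained OLS refit on the retained features, and held-out evaluation.

The constrained LASSO minimises
`(1/2n)||y - Xb - Zg||^2 + lambda sum(|b_j|)` subject to `b_j <= 0` for
biomarkers, with covariates (age, sex, scanner sequence) unpenalized and
unconstrained — retained covariates can legitimately be positive. On the
feasible set the penalty is linear, so the coordinate update has the closed
form `b_j <- min(0, (rho_j + lambda)/c_j)`, and a box-constrained
quasi-Newton solver provides an exact independent oracle the tests compare
against (along with glmnet under `upper.limits = 0`). The refit exists
because the selection stage alone provides no standard errors, p-values or
adjusted R^2; refitting the retained design by OLS is the standard
mechanism that does. Test-set performance is the Pearson correlation
between predictions and observations with a 95% Fisher-z interval
(denominator n - 3), the relative mean error
`100 (mean(pred) - mean(obs))/mean(obs)` defined on cohort means, and a
significance flag against the Bonferroni threshold alpha/m (0.05/6 =
0.008). Nested-model ANOVA compares the full refit against
family-restricted refits (cortical-only, lesion-only) by the usual F
statistic; a family that retained nothing is skipped with a flag rather
than fabricating a comparison.

## Problem sizes and numerical choices

Cohort-level analyses run on 64^3 grids at 2 mm spacing with a 6 mm ribbon:
the ribbon must span at least three voxels so that halving it keeps it
resolvable, and a 139-subject cohort processes in minutes at this size.
Single-subject shape accuracy is checked at 96^3 / 1 mm with the 3 mm
ribbon. The determinism check uses a 48^3 / 2.5 mm cohort. Tolerances worth
knowing: EM convergence 1e-4 mean posterior change (50 iteration cap,
non-convergence flagged); coordinate descent 1e-7 coefficient change; EDT
is exact (Felzenszwalb lower-envelope algorithm with a large finite
sentinel, since infinite seeds make the envelope breakpoints NaN);
morphology derives balls from the EDT so anisotropic spacing is respected
exactly; ties in nearest-anatomy attribution resolve to the first anatomy
in atlas order.

## What passing tests do and do not show

The phantoms provide exact ground truth, controllable injury, and realistic
acquisition artefacts (bias, Rician noise, between-subject anatomy), so the
test suite genuinely exercises every stage end to end — including the full
simulate -> preprocess -> segment -> shape -> ventricle -> assemble -> model
chain at n = 139. They do not emulate gyral anatomy, partial-volume mixing,
multi-site contrast differences beyond a categorical covariate, motion, or
pathology whose intensity overlaps healthy tissue; performance floors
measured here are therefore upper bounds on what the same code would achieve
on clinical data, and the cohort-level prevalence percentages are properties
of the generator, not reproductions of any patient cohort. Binary injury
rules use a one-voxel volume floor rather than a literal "greater than
0 mL", since discretisation noise would otherwise flag injury everywhere;
the z threshold is 2.5. With 24 (region, metric) cells per subject, a small
per-cell false-positive rate still flags an appreciable fraction of healthy
controls as "injured" — the same behaviour reported for normative cohorts
assessed with this family of rules.
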