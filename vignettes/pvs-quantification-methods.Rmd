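---
title: "Computational PVS quantification: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational PVS quantification: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsmorph)
```

## The problem

Perivascular spaces (PVS) are fluid-filled compartments around small
perforating vessels. On axial T2-weighted MRI they appear as thin, bright,
roughly dorsoventral tubular structures of sub-3-mm calibre, most prominently
in the centrum semiovale. Their burden is conventionally scored on an ordinal
0-4 visual scale based on the count in the single most affected slice; that
scale is quick but coarse. `pvsmorph` implements a computational alternative:
segment each PVS in a region of interest, measure it, and aggregate
per-subject metrics (count, total volume, mean length/width/size) that can be
carried into cohort-level regression models against vascular risk factors and
white matter hyperintensity (WMH) burden.

No public imaging dataset accompanies the cohort this pipeline targets, so
everything here is validated on synthetic phantoms with exact ground truth
and on simulated cohorts with known effect structure. A green test
establishes that the implementation does what its model says on data obeying
the generator's assumptions - not that the pipeline performs equally on real
scans, where gyral anatomy, bias fields and pathology intrude.

## Pipeline model and assumptions

**Reslicing.** Input volumes are 1 x 1 mm in-plane with 2 mm slices. The
pipeline reslices to 1 mm isotropic with the slice-doubling rule: original
slices are preserved bit-exactly and each inserted slice is the arithmetic
mean of its two neighbours. The output depth is `2Z - 1`: the rule defines
voxels only *between* existing slices, and we do not extrapolate a final
slice (a `pad_last_slice` flag exists for the even-count dialect). Any other
input geometry is refused rather than silently resampled. ROI masks are
resliced by nearest neighbour (averaging a mask would create non-binary
values); ties go to the lower slice.

**Vesselness.** Tubularity is scored by the multiscale Hessian filter for
bright curvilinear structures. At scale $\sigma$ the Hessian is computed by
separable convolution with sampled Gaussian-derivative kernels (reflection
boundary, kernel radius $\lceil 4\sigma \rceil$), normalised by
$\sigma^\gamma$ with $\gamma = 2$. With eigenvalues ordered
$|\lambda_1| \le |\lambda_2| \le |\lambda_3|$,

$$V = \begin{cases}
0 & \lambda_2 > 0 \text{ or } \lambda_3 > 0\\[2pt]
\left(1 - e^{-R_A^2/2\alpha^2}\right)
e^{-R_B^2/2\beta^2}
\left(1 - e^{-S^2/2c^2}\right) & \text{otherwise,}
\end{cases}$$

with $R_A = |\lambda_2|/|\lambda_3|$, $R_B =
|\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ and $S = \sqrt{\sum_i \lambda_i^2}$.
Responses are combined across scales by per-voxel maximum *before*
thresholding.

Parameter defaults, all exposed in configuration:

| parameter | default | why |
|---|---|---|
| `scales_sigma` | 0.4, 0.7, 1.0, 1.3 voxels | covers apparent widths of roughly 0.5-2.5 voxels, the calibre band of centrum semiovale PVS on a 1 mm grid; acts as the soft width constraint |
| `alpha`, `beta_b` | 0.5, 0.5 | the filter literature's standard discriminator weights |
| `c` | `"auto"` = half the max of $S$ over the ROI per scale | adapts structureness to image contrast; errors on zero-curvature input instead of guessing |
| `gamma_norm` | 2 | standard scale normalisation; consistent with the brute-force oracle used in tests |
| `threshold` | 0.25 | applied to the combined response in $[0,1]$ |

The original optimisation of scales and threshold against ordinal visual
ratings was performed in prior work and is not printed anywhere we can verify
against, so these defaults are the package's own documented choices.

Two numerical caveats are deliberate. The sampled second-derivative kernel is
corrected to sum exactly to zero, so a constant image has an exactly zero
Hessian. And for sub-voxel scales ($\sigma < 0.7$) the sampled kernels
overestimate curvature relative to the $\sigma^2$ normalisation (sub-voxel
aliasing); $\sigma = 0.4$ is retained for sensitivity to the thinnest PVS,
but scale-sweep unimodality is only asserted for $\sigma \ge 0.7$.

**Segmentation and morphological constraints.** The thresholded field is
labelled with 26-connectivity (thin oblique tubes fragment under
6-connectivity; 6 is available in configuration). Accepted PVS must have
major-axis length between 3 and 50 mm inclusive (the permissive reading of
"between") and at most 1000 voxels - the approximate volume of a cylinder of
radius 2.5 and length 50 voxels ($\pi \cdot 2.5^2 \cdot 50 \approx 982$,
rounded to the nearest hundred), which separates PVS from blob-like WMH.
Width is *not* re-applied as a hard rule; the scale band constrains it
softly. Every rejection is logged with the rule that fired, and accepted +
rejected always equals extracted.

**Quality control** is advisory and automated (the original accept/reject
was human): `noise_suspect` when the segmented fraction of the ROI exceeds a
configurable 5%, `empty_roi` below a voxel floor, `blob_suspect` when an
accepted component has length/width < 1.5. Flags never auto-drop a subject.

**Morphometry.** Each component is summarised by the ellipsoid of equal
second moments: the population covariance of its voxel centres plus a
$1/12$-per-axis voxel-extent correction, with axis length $4\sqrt{\lambda}$.
"Length" is the major axis, "width" the second. The correction makes
degenerate inputs well defined: one voxel measures $4\sqrt{1/12} \approx
1.155$ mm on every axis, and an $N$-voxel straight line measures
$4\sqrt{N^2/12} \approx 1.155 N$. That last identity matters for validation:
*the convention reads an ideal rod of physical length $L$ as
$4\sqrt{(L^2+1)/12} \approx 1.155L$.* Phantom-recovery tests therefore score
segmentation fidelity against this convention-consistent expectation (and
widths against the tube profile's FWHM, $2\sqrt{2\ln 2}\,\sigma_r$), not
against raw geometric length - otherwise the fixed +15.5% convention factor
would masquerade as segmentation error. Measured fidelity on the standard
phantom battery is about +1% for length and +16% for width, inside the 15% /
25% acceptance bands.

**Emulated visual rating.** Components are counted per axial slice and
hemisphere (a component is "in" a slice if any voxel is; hemispheres split at
the ROI x-centroid - the source scale defines neither, so both choices are
documented here), the maximum is taken, and banded 0 / 1-10 / 11-20 / 21-40 /
>40 into the 0-4 scale.

## The synthetic world

`generate_volume()` draws straight bright tubes with a Gaussian radial
profile sampled at voxel centres (what a Hessian filter assumes), *flat
ends* (so truth length is exact, rather than spherical caps that would
lengthen every tube), orientation within 40 degrees of the through-plane
axis (centrum semiovale vessels run roughly dorsoventrally), placed with
clearance inside a rectangular ROI in native anisotropic space - so
reslicing is genuinely exercised. Optional spherical blobs emulate WMH
confounders; `parallel_streaks` adds thin bright lines along the phase axis
mimicking the motion artefacts that plague real acquisitions (used to
exercise QC only). Noise is Gaussian or Rician (magnitude of signal plus
complex Gaussian). Default geometry is the target acquisition (256 x 256 x
80 at 1 x 1 x 2 mm) and the default tube count 258 matches the cohort's mean
per-subject PVS count; tests use smaller grids with proportionally fewer
tubes for speed, and say so.

What the generator does *not* emulate: brain anatomy, bias fields,
multi-contrast appearance, curved or branching vessels, partial-volume
against anatomical boundaries. Recovery results are therefore upper bounds
on real-data performance.

`simulate_cohort()` generates per-subject rows from a latent PVS-burden
score: continuous metrics are linear loadings on the latent (loadings 0.7-0.9
chosen to mirror the observed correlation pattern among count, volume, size);
binary risk factors follow logistic models with configurable per-SD log-odds;
WMH %ICV follows a beta distribution with logit-linked mean (intercept -4.6
puts the mean at ~1% of ICV, precision 50 reproduces the observed skew); the
0-4 rating comes from cutpoints (-2.5, -1.0, 0.8, 2.2) on the latent, chosen
to reproduce the observed rating distribution (mean ~2.1). Binary prevalences
default to the cohort's: hypertension 47.65%, diabetes 9.57%,
hypercholesterolemia 39.21%, CVD 28.33%, stroke 17.64%. The hidden
`latent_burden` column is kept for parameter-recovery tests and has no
real-data counterpart.

## Statistical battery

- `squeeze_transform()`: $y^* = (y(n-1) + 0.5)/n$, applied to the whole
  vector (the transform's standard usage, not only to zeros); affine,
  order-preserving, fixed point 0.5.
- `fit_linear()`: OLS with the PVS predictor z-scored and (by default) the
  outcome z-scored, so the reported effect is a standardized beta. The
  source analysis's z-transform sentence is ambiguous about its referent;
  z-scoring the predictor everywhere and continuous outcomes in linear
  models is the reading consistent with reported standardized effects, and
  `z_outcome` is switchable.
- `fit_logistic()`: ML logistic fit, OR per SD with Wald 95% CI; explicit
  errors on degenerate outcomes and (quasi-)perfect separation.
- `fit_beta_regression()`: joint ML of $(\beta, \log\phi)$ for
  $y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$, $\mathrm{logit}(\mu) =
  X\beta$, by BFGS from logit-scale OLS starts; SEs from the observed
  information; boundary responses are refused with a pointer to the squeeze
  transform.
- `polyserial_corr()`: two-step latent-bivariate-normal estimator -
  thresholds from inverse-normal cumulative proportions, then 1-D ML for
  $\rho$; Wald CI from the profile curvature.
- Covariate rule: age, sex and hypertension are controlled for, excluding
  whichever is the outcome of interest. Complete-case analysis; Fazekas
  total treated as continuous in linear models; no multiplicity correction
  (all results reported).
- `compare_models()`: "practical improvement" iff the candidate's BIC beats
  the visual-rating reference by >= 10 *and* its AIC is smaller;
  non-overlapping effect CIs flag a significant difference in effects.

## Known limitations

- The NIfTI reader/writer covers only the subset this pipeline emits (3-D,
  diagonal orientation); it is not a general NIfTI implementation.
- Acceptance testing of the end-to-end cohort pattern asserts each pattern
  element in >= 90% of 50 seeds; a joint assertion is statistically
  unattainable because two independent nominal-5% null checks alone bound
  the joint rate at ~0.90 in expectation.
- Sub-voxel filter scales are kept for sensitivity but their responses are
  quantitatively unreliable (aliasing); widths below ~1 voxel are reported
  on the convention's scale, not as calibrated physical calibres.
- Real-data claims (registration quality, human QC, multi-contrast WMH
  exclusion) are out of scope; ROI masks are inputs here.
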