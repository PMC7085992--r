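---
title: "Quantifying whole-psoas structure and FDG uptake from PET/CT: methods and design"
author: "psoasPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-psoas structure and FDG uptake from PET/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoasPET)
```

## The measurement problem

Sarcopenia metrics are usually read off a single CT slice at the level of
the third lumbar vertebra. This package instead quantifies the *whole
recognizable psoas muscle* from a co-registered FDG PET/CT study, between
an operator-chosen cranial bound (the soma of D12) and the plane of the
L5--S1 junction, and couples the structural read-out with the muscle's
metabolic pattern:

* **volume** in mL, and normalized to Robinson ideal body weight (IBW,
  mL/kg), to remove the trivial dependence on body size;
* **AAC**, the average attenuation coefficient (mean HU over the muscle
  mask), an index of muscle quality;
* **SUV and N-SUV**: mean standardized uptake value over the muscle
  voxels, divided by the subject's mean liver SUV to absorb scanner
  sensitivity differences;
* **VC-SUV**, the coefficient of variation (100 x SD/mean, in %) of the
  per-voxel N-SUV pooled over both psoas bodies -- the heterogeneity
  index;

and finally asks which of these indices carries prognostic information in
an ALS cohort, via median-split Kaplan--Meier curves, log-rank tests, and
univariate plus backward-eliminated multivariate Cox models.

## The segmentation algorithm

Per axial CT slice in the configured range, four steps run in sequence.

1. **Windowing + histogram equalization.** HU values are clamped to a
   soft-tissue body window (default [-200, 300] HU) and mapped through
   the empirical CDF of the windowed slice. Output is in [0, 1], ranks
   are preserved, and the map is invariant to HU shifts that keep tissue
   inside the window. Equalization is global per slice; adaptive variants
   (CLAHE) would alter the method, so they are deliberately not offered.

2. **Canny edge detection.** Gaussian smoothing (sigma = 1.4 px), Sobel
   gradients, non-maximum suppression along the quantized gradient
   direction, hysteresis thresholding. Two implementation details matter
   for quantitative work:

   * thresholds are *relative to the slice's maximum gradient magnitude*
     (the MATLAB convention), so they survive intensity rescaling; the
     defaults (low 0.012, high 0.03) were calibrated on the package's
     digital phantoms, where the muscle--fat step after equalization is a
     few percent of the strongest (air--body) edge;
   * the ridge position is refined to sub-pixel accuracy by parabolic
     interpolation of the gradient magnitude along the gradient
     direction, and ties on ideal symmetric steps resolve to the
     brighter-side pixel. Without this refinement the contour sits on
     pixel centres up to half a pixel inside the true boundary, which
     biases volume by several percent and lets fat voxels leak into the
     attenuation average.

3. **Alpha-shape contour closure.** Edge pixels around a muscle form a
   nearly closed chain with gaps where contrast drops. The closure keeps
   every Delaunay edge whose smallest empty circumscribing disc has
   radius at most r = 1/alpha -- including the *singular* edges that
   reconstruct a sampled curve -- removes edges interior to the filled
   complex, and extracts the bounded faces of the resulting planar graph.
   A gap of width g is bridged once 2r >= g. As alpha tends to 0 the
   graph degenerates to the convex hull. A subtlety discovered during
   phantom testing: a triangle-only alpha-complex cannot represent a
   1-px-wide chain (three nearly collinear pixels have an arbitrarily
   large circumradius), so the face-based construction over the full
   1-skeleton is essential, not cosmetic.

   By default alpha is auto-tuned per slice and side: the smallest disc
   radius whose complex has a closed face containing the tracking point.
   This closes each gap with the smallest disc able to do so and keeps
   neighbouring structures (vertebral cortex, bowel) disconnected.

4. **Tracked region selection.** On the first slice the operator's seed
   points identify the two psoas bodies; afterwards each side is tracked
   by its contour centroid. Among candidate faces, those containing the
   tracking point and with an area between 0.5x and 2x the previous
   slice's area are admissible, and the *innermost* (smallest) one is
   selected -- the inner muscle, not an enclosing body outline. A side
   with no admissible candidate is repaired by copying the nearest
   selected contour, for at most `kMissing = 2` consecutive slices;
   longer runs abort with an error naming the slices.

Selected contours are rasterized with the even-odd rule (a pixel belongs
to the muscle if its centre is inside the polygon); an optional
`contourInset` parameter (default 0, px) shrinks the contour along its
inward normals before rasterization for users who prefer the region
strictly interior to the ridge line.

The operator's original visual-inspection step is replaced by explicit
configuration (slice bounds plus two seed points) so that every run is
reproducible without an operator in the loop.

## From CT mask to PET metrics

The CT grid is finer than the PET grid (1 mm vs 4 mm in-plane here), so
the mask must be transferred across resolutions. For every PET voxel the
*exact* volume fraction of its physical box covered by CT mask voxels is
computed -- the grids are axis-aligned, so the 3D overlap separates into
per-axis interval overlaps and the computation reduces to three small
matrix contractions. A PET voxel enters the PET-grid mask when its
covered fraction reaches `fracThreshold` (default 0.5) and takes the side
label with the larger coverage. This choice conserves volume (for a
locally straight boundary, coverage >= 0.5 coincides with
centre-inside), is monotone in the threshold, and is testable against a
brute-force per-voxel oracle. PET values at included voxels are used
as-is, with no interpolation.

SUV is computed voxelwise as concentration (kBq/mL) x body weight (kg) /
injected dose (MBq); concentrations are assumed scanner-decay-corrected,
as is standard for clinical PET, and negative reconstruction artifacts
are clamped to zero with a logged count. The liver normalizer is either a
supplied mask's mean SUV or a 30-mm-diameter sphere at a configured
centre. VC-SUV uses the sample (n-1) SD -- immaterial at thousands of
voxels, but fixed for determinism -- and is identical on SUV or N-SUV
voxels since the normalizer cancels. Myocardial N-SUV over a supplied
left-ventricular mask enforces a minimum VOI of 10 mL; the companion
cohort reports an *average* LV VOI of 6 +/- 3 mL alongside that stated
minimum, an internal tension we resolve by enforcing the explicit
minimum and erroring below it.

Robinson's ideal body weight is 52 kg (male) / 49 kg (female) at 60
inches plus 1.9 / 1.7 kg per inch above 60, with heights at or below 60
inches returning the base weight.

## Survival analysis

For each of the seven stratification variables (age, ALSFRS-R, spinal
cord N-SUV, psoas volume/IBW, psoas N-SUV, psoas VC-SUV, BA4 SUV) the
cohort is split at the median -- the order-statistic midpoint for even n,
ties going to the low group, so "low" means <= median. Kaplan--Meier
curves, the log-rank test, and Cox models are delegated to the
`survival` package with Breslow tie handling and Wald 95% CIs; the
univariate model fits the above-median indicator (a continuous option is
exposed). The step-down multivariate procedure refits the model without
each variable in turn, computes the 1-df likelihood-ratio p, and removes
the worst variable while its p exceeds 0.1; an empty final model is a
legitimate outcome. Mortality rates are printed as nearest-integer
percentages with halves rounded down, matching the reference cohort's
table (21/56 prints as 37%). Significance is two-sided 0.05 throughout
with no multiplicity correction, and a Schoenfeld-residual hook
(`schoenfeldCheck`) is exposed for proportionality diagnostics without
being part of the pipeline.

Subjects alive at last contact are censored at their follow-up time;
subjects lost to follow-up are simply absent from the cohort table.

## The digital phantom and what it does (not) show

`generatePhantom()` builds a paired CT/PET study with analytic ground
truth: an elliptic body outline filled with fat-like tissue (-80 HU), a
vertebral block (700 HU), two tapered elliptic-cylinder psoas bodies
(39.4 HU; SUV 0.9 with a 7.2% voxel SD, i.e. VC-SUV 8%), and a liver
ellipsoid (60 HU; SUV 2.0), on a 256 x 256 x 40 CT grid at 1 x 1 x 3 mm
and a 64 x 64 x 40 PET grid at 4 x 4 x 3 mm whose origin is shifted a
few mm against the CT grid so the box-overlap downsampler is exercised on
non-nested voxels. A voxel's tissue is decided by its centre; PET values
are stored as concentration so `computeSUV()` round-trips through the
scan metadata. Noise is additive Gaussian per modality (default 0):
the package tests image-domain analysis, not reconstruction, so Poisson
projection noise and scanner PSF modelling are out of scope.

Passing the phantom recovery checks (per-side Dice >= 0.90, volume
within 10% of the analytic cylinder volume, AAC within 0.5 HU, N-SUV
within 2% relative, VC-SUV within 1 CV point, on the noise-free phantom)
demonstrates that the *computational chain* is faithful. It does not
demonstrate robustness to the things real CT brings -- texture, partial
volume at oblique boundaries, anatomical variation, contact between the
psoas and neighbouring soft tissue of identical attenuation -- and the
Canny thresholds that are comfortable on the phantom will generally need
per-protocol tuning on clinical data.

`generateCohort()` simulates subject tables at the reference study's
conditions: n = 56, covariate means/SDs from the published cohort
summaries, exponential survival with proportional hazards on
above-median indicators, uniform 2--60-month follow-up windows, and a
baseline hazard solved so the expected null event fraction matches
1 - `censoringRate` (default 37.5% deaths). With `censoringRate = 0`
follow-up is unbounded and the baseline is set from the reference
cohort's 22-month median follow-up.

## Simulation design choices

Two replicated studies quantify the survival module.

* **CI coverage.** Cohorts are two-group exponentials in which the
  hazard is driven by the *sample*-median-split indicator -- the exact
  covariate the univariate model fits -- so the fitted coefficient
  estimates the generative log HR without the attenuation that a
  population-median assignment would introduce through near-median
  misclassification. Coverage of the Wald 95% CI is then a clean
  property of the estimator (n = 500, HR 2, ~20% censoring, 200
  replicates).

* **Backward-elimination retention.** Cohorts at the reference size
  (n = 56) with HR 5 on a single variable's indicator. The true variable
  should essentially always survive elimination. Note an arithmetic
  fact about the *retained-alone* probability: each of the six
  conditionally-null covariates ends the step-down with p <= 0.1 with
  probability close to the removal threshold, so the chance that none
  survives is about 0.9^6, i.e. roughly one half. A step-down procedure
  at removal p = 0.1 therefore cannot deliver a near-certain
  single-variable final model, whatever the effect size; the package
  reports the retained-alone fraction as measured rather than
  engineering around it.

## Numerical choices and degenerate inputs

* Slice ranges are 1-based half-open `[sliceStart, sliceStop)` -- the
  half-open arithmetic of the design rendered in R's 1-based indexing.
* Constant CT slices equalize to constant 0 (logged); flat gradient
  fields (max magnitude below 1e-10) yield an empty edge set.
* Near-duplicate sub-pixel edge points are deduplicated at 1/128 px, and
  a deterministic sub-milli-pixel jitter retries the triangulation if
  the Delaunay backend still hits a degeneracy; collinear point sets are
  a hard error.
* Rasterization conflicts (a pixel claimed by both sides) keep the first
  (left) label; with the default geometry the two bodies never touch.
* The overlap downsampler treats each voxel as the closed box of size
  `spacing` centred on the voxel centre; inclusion uses a 1e-12 slack so
  exact 50% coverage is included.
* Problem sizes in the test-suite: reduced 12-slice phantoms for unit
  tests, the full 40-slice phantom in the acceptance checks; simulation
  studies use 200 replicates at n = 500 (coverage) and 100 replicates at
  n = 56 (retention). These sizes make the whole suite comfortably
  reproducible on a laptop while keeping Monte-Carlo error well inside
  the margins being tested.

## Known limitations

* NIfTI-1 is the only on-disk volume format; DICOM series are not read.
  The CT rescale arithmetic is available as `applyRescale()` for users
  converting DICOM upstream.
* The segmentation assumes the two psoas bodies are the innermost closed
  contours around the seeds and that contrast to surrounding tissue
  produces a mostly closed Canny chain; muscles fused with
  iso-attenuating neighbours over long stretches will defeat the
  area-ratio tracking.
* Spinal-cord and motor-cortex uptake enter the cohort analysis as
  supplied columns (or ROI means over supplied masks); their extraction
  pipelines are out of scope.
* No competing risks, time-varying covariates, or frailty terms; the
  proportionality assumption is checkable but not enforced.
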