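# psoasPET

Whole-psoas-muscle structure and FDG metabolism from PET/CT, with
prognostic survival models.

## What it does, and for whom

Muscle mass is usually assessed on a single CT slice at L3. For studies
that need the *whole* muscle — e.g. relating skeletal-muscle metabolic
state to disease progression in amyotrophic lateral sclerosis (ALS) —
this package extracts both psoas bodies from an axial CT stack between
operator-chosen cranial (D12) and caudal (L5–S1) bounds, carries the mask
onto the co-registered PET grid, and computes per-subject indices:

| index | definition |
| --- | --- |
| volume | mask voxels × voxel volume, in mL and mL/kg of Robinson ideal body weight (IBW) |
| AAC | mean CT attenuation over the mask, HU |
| SUV | mean of voxelwise `conc(kBq/mL) × weight(kg) / dose(MBq)` |
| N-SUV | SUV / mean liver SUV |
| VC-SUV | 100 × SD/mean of per-voxel N-SUV, both bodies pooled (%) |

Segmentation is slice-wise: histogram equalization inside a body HU
window, Canny edge detection with sub-pixel ridge refinement, α-shape
closure of the edge chain (the bounded face of the α-complex containing
a tracked seed point), and centroid/area-ratio tracking across slices.
The CT mask is downsampled to the PET grid by exact voxel box overlap
(a PET voxel is included when ≥ 50% of its physical box is covered).

The cohort layer stratifies survival by the median of each candidate
biomarker (age, ALSFRS-R, spinal cord N-SUV, psoas volume/IBW, psoas
N-SUV, psoas VC-SUV, motor-cortex SUV): Kaplan–Meier curves, log-rank
tests, univariate Cox models on the above-median indicator, and a
step-down multivariate Cox model that removes variables with
likelihood-ratio p > 0.1.

A digital PET/CT phantom generator and a cohort simulator with known
prognostic structure make every stage testable with no external data.

## Worked example

Generate a phantom study, segment it, and extract the subject metrics:

```r
library(psoasPET)

spec <- phantomSpec(seed = 7)              # 256x256x40 CT, 64x64x40 PET
ph   <- generatePhantom(spec)
cfg  <- phantomSegmentationConfig(spec)    # seeds + slice bounds
mask <- buildMask(ph$ct, cfg)
suv  <- computeSUV(ph$pet, ph$meta)
extractRoiMetrics(ph$ct, suv, mask, ph$meta,
                  liverCenter = spec$liverCenter)
#> RoiMetrics
#>   volume: 170.90 mL (2.41 mL/kg IBW)
#>   AAC: 39.4 HU
#>   SUV mean: 0.900; N-SUV: 0.450 (liver 2.000); VC-SUV: 8.17%
#>   voxels: 56968 CT, 3564 PET
```

The phantom's generative values are muscle HU 39.4, muscle SUV 0.9
against liver SUV 2.0 (N-SUV 0.45), and a voxel SUV spread of 8%: the
pipeline recovers attenuation exactly and the metabolic indices to a
fraction of a percent; the volume (170.9 mL) is within 0.3% of the
analytic cylinder volume over the segmented slices.

Simulate a 56-subject cohort in which only spinal-cord N-SUV drives the
hazard (true HR 5 on the above-median indicator) and analyse it:

```r
cohort <- generateCohort(n = 56, logHR = c(spinal_cord_n_suv = log(5)),
                         seed = 7)
tab <- outcomeTable(cohort)
subset(tab$univariate, variable == "spinal_cord_n_suv")
#>           variable    median group  n deaths mortality_pct hazard_ratio ci95_low ci95_high     p_value
#>  spinal_cord_n_suv 0.8286019   low 28     16            57           NA       NA        NA          NA
#>  spinal_cord_n_suv 0.8286019  high 28     22            79     2.989356 1.485226   6.01676 0.002152533
tab$multivariate$retained
#> [1] "spinal_cord_n_suv" "psoas_volume_mL_per_kg" "psoas_n_suv"
```

The cohort splits 28/28 at the median; the above-median group has the
higher mortality and a univariate hazard ratio of 3.0 (95% CI 1.5–6.0).
The step-down model keeps the truly prognostic spinal-cord variable
(multivariate HR 3.3); at n = 56 a couple of null variables can also end
the step-down with p ≤ 0.1, as here.

For scripted use, `inst/cli/psoaspet.R` exposes the stages as commands
(`simulate`, `segment`, `metrics`, `survival`, `pipeline`), each writing
its artifacts plus a manifest (inputs, checksums, seed, package version)
for exact re-runs.

## Vignette

`vignettes/psoasPET-methods.Rmd` documents the algorithms, the tunable
parameters and their defaults, the phantom and cohort simulators, the
numerical edge cases, and the known limitations.
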