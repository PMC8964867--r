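---
title: "Evaluating perturbation impact on normative atrophy z-score maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating perturbation impact on normative atrophy z-score maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophyz)
```

## The evaluation model

Normative single-time-point atrophy estimation works in three steps. A
reference cohort of healthy subjects is preprocessed into spatially
normalized, modulated, smoothed gray-matter (GM) density maps on a common
grid. For a target sex and age, voxel-wise mean and SD templates are
estimated from the reference subjects of that sex whose age falls in the
closed window `age ± 2` years (sample SD, `n − 1` denominator). A subject's
atrophy map is then the voxel-wise z-score against those templates,
restricted to a GM analysis mask; `z` in `[−2.5, 2.5]` is conventionally
read as volume change within expected limits.

`atrophyz` measures how an image modification changes that readout. Two
processing conditions A and B of the same subject are both z-scored, and
their difference is summarized by the mask-wise RMSE
`sqrt(mean((z_A − z_B)^2))`. Context for the size of an RMSE comes from a
test–retest benchmark: the RMSE distribution between two unmodified
same-session acquisitions. Impacted cases are flagged two ways:

* **benchmark percentile** — RMSE strictly greater than the 75th percentile
  of the benchmark distribution (linear interpolation between order
  statistics, the quantile at rank `1 + (n − 1) p`);
* **iterative Grubbs** — the two-sided maximum normalized residual test
  `G = max |x_i − mean(x)| / sd(x)` with critical value
  `((n−1)/sqrt(n)) * sqrt(t² / (n−2+t²))`, `t` the upper `α/(2n)` Student-t
  quantile with `n − 2` df, applied iteratively (remove, retest) until no
  outlier remains or fewer than 3 observations are left.

Spatial structure is summarized by a deviation map: per voxel, the absolute
value of the subject-mean signed difference `|mean(Δz)|`. We read "absolute
mean difference" literally as the magnitude of the signed mean; the
alternative `mean(|Δz|)`, which forbids cancellation across subjects, is
available via `deviation_map(..., method = "mean_abs")`.

## The synthetic phantom

No real imaging is involved; every input is generated by the package.

**Geometry.** The brain support is an axis-aligned ellipsoid occupying 60%
of each grid dimension, slightly posterior-inferior of centre so that an
anterior-inferior "face-exterior" slab fits inside the field of view.
Regions are geometric sectors of the ellipsoid — frontal, frontobasal,
temporal (bilateral inferior-lateral), occipital, cerebellum
(posterior-inferior) and a central deep ball — pairwise disjoint and
reproducible without any atlas download. The face-exterior slab is disjoint
from the brain support by construction; it exists so that perturbations can
be placed strictly outside the analysis mask.

**Density model.** The noise-free GM density is a paraboloid profile
(peak 0.85 at the ellipsoid centre, 0 at its surface), scaled by a small
multiplicative sex offset (±2%) and reduced linearly with age at
`age_slope_amplitude` density units per year at the peak (default 0.003,
i.e. roughly 0.35%/year — the magnitude of adult GM decline reported in
volumetric aging studies), centred at a fixed reference age of 40 years.
Each subject adds a smooth Gaussian random field (white noise filtered at
`smoothness_fwhm = 8` mm FWHM, rescaled to point SD `subject_sd = 0.05`)
plus white scan noise (`noise_sd = 0.02`), and densities are clipped at 0.
Smoothing uses a separable Gaussian kernel with zero boundary; random
fields are rescaled by the theoretical interior attenuation factor, so the
point SD is exact away from the volume edge (the brain sits in the
interior).

**Demographics.** `cohort_spec()` defaults emulate a large community
normative cohort at reduced n: 65% female, ages 18–77 from a truncated
normal with mean 46.3 and SD 17.1 years. For template building across many
strata at desk scale, the default experiment instead samples reference ages
uniformly over the patient age range widened by the template window, with
`n = 600`; this keeps every sex/age stratum comfortably above `min_n = 10`
(expected ≈ 35 subjects in the rarer sex per stratum), which the
truncated-normal shape cannot guarantee below cohort sizes in the
thousands. The experiment aborts with a configuration-level error before
processing any patient if a needed stratum is short.

**Patients.** Patient scans start from the mean model for their age/sex and
get atrophy planted by reducing density inside named regions by
`effect × local template SD`, so the planted voxel-level z-effect is known
by construction (default: temporal, effect 2.5 — at the boundary of the
expected-limits convention). When a template object is supplied its `sd_map`
is used, making recovery exact up to template sampling error; otherwise the
generator's theoretical point SD `sqrt(subject_sd² + noise_sd²)` stands in.

**Test–retest.** A repeat acquisition adds an independent smoothed zero-mean
noise field of point SD `repeat_sd`. The benchmark simulates *two*
acquisitions of a noise-free anatomy, because in a real test–retest pair
both scans carry their own acquisition noise; the expected benchmark RMSE
under a spatially constant template SD `s` is therefore
`sqrt(2) · repeat_sd / s`. The default `repeat_sd = 0.0107` places that
expectation near 0.28 z-units given the default reference variability
(`s ≈ 0.054`) — a realistic operating point for same-session repeat
variability of this readout.

**Perturbations.** Defacing and acceleration effects are injected directly
on the GM map as, in fixed order: multiplicative global scaling, an
additive Gaussian bias field `A · exp(−d²/2σ²)` centred on a region
centroid or voxel, a sub-voxel translation along the fixed diagonal
direction by trilinear interpolation, optional fractional erosion inside a
region, then clipping at 0. Each perturbation can "crash" with probability
`failure_prob`; failures are typed outcomes counted separately from
statistics, never exceptions. The six shipped presets are illustrative
operating points spanning the qualitative spectrum — a strong frontobasal
bias exceeding the benchmark threshold, moderate and weak biases, a 1%
global intensity shift, a crash-prone method, and perturbations confined to
the face-exterior slab — not calibrated models of any particular tool,
since no quantitative model of how specific defacing tools corrupt GM maps
exists.

## Numerical and design choices

* Template SDs use the sample (n−1) estimator; a stratum with one subject
  is an error, as the SD is undefined.
* The age window is a closed interval on floating-point ages; template
  target ages are rounded patient ages, with caching per (sex, rounded age).
* The analysis mask is derived once from a pooled template of the whole
  reference cohort (`mean > 0.1`, `SD > 1e-6`) and shared by all subjects,
  mirroring a single workflow-level GM mask; the SD floor drops
  near-degenerate voxels from the analysis instead of z-scoring them as 0.
* Off-mask voxels are stored as missing (NaN in NIfTI), never 0.
* Grubbs defaults: `α = 0.05`, two-sided — the standard convention where no
  level is otherwise stated — surfaced in the configuration. Ties at the
  maximum deviation flag the lowest index. Iteration stops below n = 3, and
  a constant remainder (zero SD) terminates the iteration with no flag:
  a constant sample contains no outlier, and all-zero RMSE vectors occur
  legitimately (identity or out-of-mask perturbations).
* The benchmark criterion uses strict `>` at the threshold, so a value
  exactly at the 75th percentile is not flagged.
* Every generator is a pure function of its seed and parameters; the
  experiment derives child seeds from the master seed by a fixed affine
  hash, and per-method results depend only on each method's own
  specification, so permuting the method list permutes report rows without
  changing any number. Reruns from the same configuration are byte-identical.

## Problem sizes

The default experiment uses a 32³ grid at 4 mm (a deliberately coarse
stand-in for template space), 600 reference subjects, 30 patients and 30
benchmark subjects — sizes chosen so a full run completes in seconds on a
laptop while keeping per-stratum template estimates stable. The noise
calibration analysis uses a 64³ grid with 50 subjects, where the RMSE
concentrates tightly enough to verify the `sqrt(2)·σ/s` law within a few
tenths of a percent.

## What the tests do and do not show

Passing this suite establishes the *machinery*: z-scores recover planted
effects at known magnitude; the RMSE, Grubbs and percentile criteria match
their definitions and calibrations; perturbations outside the mask have
exactly zero impact; the pipeline is deterministic and internally
consistent. It does not establish anything about real defacing tools or
real MRI: the phantom has no skull, no misclassification of background into
tissue classes, no preprocessing (segmentation/normalization/modulation)
whose failure modes defacing could trigger, no scanner or site
heterogeneity, and its anatomy is an ellipsoid, not a brain. Perturbation
presets named after qualitative behaviours are design points, not measured
tool signatures. Conclusions about specific tools require the real
pipeline on real data; this package provides the controlled reference
implementation of the measurement itself.
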