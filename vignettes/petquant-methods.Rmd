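---
title: "Methods: models, parameters, and validation design in petquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and validation design in petquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

petquant processes reconstructed dynamic PET acquisitions up to the point of
statistical analysis: coregistration to a T1-weighted MR image, partial-volume
correction (PVC), tracer kinetic quantification, automated quality control
(QC), and long-format reporting. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices behind the
built-in synthetic validation phantom. Everything stated here about accuracy
is computed by the package's own test suite and acceptance script; nothing is
quoted from external measurements.

## Conventions and assumptions

Time is minutes everywhere (BIDS sidecar timing in seconds is converted at
read time), because tracer rate constants are conventionally expressed in
min^-1. Activity is kBq/mL. Voxel indices are 0-based and world coordinates
follow the NIfTI RAS-mm affine. Input PET series are assumed decay-corrected
during reconstruction — the package performs no decay handling. Resampling
outside the source field of view yields 0, not NA; downstream masks exclude
the field edge anyway.

## Rigid coregistration

PET-to-T1 alignment uses a six-parameter rigid transform (rotations in
degrees applied intrinsically z-y-x about the moving image's intensity
center of mass, then translations in mm), optimized by maximizing normalized
mutual information, NMI = (H(A)+H(B))/H(A,B), which ranges from 1
(independent) to 2 (identical partitioning). The procedure is hierarchical:

* **Phase 0** translates the PET so the intensity centers of mass coincide.
* **Stage 1** registers the two binary head masks, treated as 0/1 intensity
  images, through the coarse pyramid levels (8 and 4 mm FWHM smoothing).
* **Stage 2** refines on the intensity images through the full pyramid
  (8, 4, 2 mm), with the joint histogram restricted to the union of the two
  head masks.

The joint histogram uses 64 bins spanning each volume's 1st-99th in-mask
percentile range (robust to hot voxels); histogram support is additionally
bounded to a 16 mm neighbourhood of the fixed head mask, the practical field
of view of the alignment. NMI under hard binning is not smooth, so each
pyramid level runs a derivative-free pattern (coordinate) search: initial
steps of half the level's FWHM, halved after each sweep without improvement,
down to a 1e-3 parameter tolerance or 200 objective evaluations per level,
with ties broken toward the smaller-magnitude parameter vector. Candidate
steps whose mask overlap falls below 10% are rejected outright. The PET head
mask defaults to an Otsu threshold on the time-weighted average volume,
keeping the largest 6-connected component, followed by a morphological
closing; a supplied brain mask is preferred for the T1 (Otsu is only a
fallback, since brain extraction is out of scope).

The pyramid and optimizer schedule are the package's own design — classic
multi-resolution registration tools do not publish a single canonical
blur/step schedule — and are validated by self-recovery rather than by
matching another implementation's output: on noiseless phantom renders, perturbations up to
10 mm / 8 degrees are recovered to within 1 mm / 1 degree (the registration
acceptance test), and the recovered optimum dominates 100 seeded random
perturbations of ±5 mm / ±5 degrees. Registration behaviour under noise is
exercised separately by the QC injection experiment, where misalignment
detection — not sub-millimetre accuracy — is the requirement.

## Partial-volume correction

Scanner blur is modelled as a spatially invariant Gaussian point-spread
function (PSF) given by its FWHM in mm (sigma = FWHM / (2 sqrt(2 ln 2))),
applied as a separable, kernel-normalized convolution with zero-padded
boundaries (kernel truncated at 3.5 sigma; total activity is conserved to
better than 0.1% for structures at least 3 sigma from every edge).

**GTM.** The geometric transfer matrix method corrects regional mean
activities: `W[i, j]` is the mean over region *i* of the blurred indicator
of region *j*, and the corrected activities solve `W t = o` per frame.
Blurred indicators are renormalized by the blurred all-ones volume so the
weights form an exact partition of unity on the finite field of view, and
background (label 0) is always included as an explicit region — whether the
background belongs in the matrix is a genuinely open choice, and including
it keeps every row summing to 1 and the system well-posed when regions tile
the volume. The solve is a direct linear solve with condition monitoring
(condition estimate above 1e8 raises an error asking for merged regions);
no non-negativity constraint is applied, and negative recovered activities
are flagged rather than clipped. On a noiseless piecewise-constant phantom
blurred with the matched PSF, GTM inversion is exact to solver tolerance —
this is the mechanism behind corrected recovery ratios near 1.

**Anatomically constrained iterative deconvolution.** The voxelwise
correction iterates the damped Van Cittert update
`f_{k+1} = S[f_k + alpha (g - G f_k)]` from `f_0 = g`, where `G` is the PSF
blur and `S` smooths each voxel over same-label neighbours only (Gaussian
kernel renormalized within the label), controlling noise amplification
without smearing activity across anatomical boundaries. The published
description of this family of methods is qualitative at the level we
implement; the update above is a faithful reconstruction, not a bit-match.
Defaults — 10 iterations, alpha = 1, 2.5 mm smoothing FWHM, and a 1e-4
relative-change stopping rule — are exposed in the function signature. The
blur residual is non-increasing over iterations on noiseless input (tested).

## Kinetic quantification

All models consume time-activity curves (TACs) on frame mid-times, with
running integrals computed as 0-anchored trapezoids (activity is anchored
at 0 at t = 0, reflecting injection at scan start). Arterial input curves
are resampled to frame mid-times by
linear interpolation. Four models are implemented:

* **Logan plot** (reversible tracers): OLS of `∫C_t / C_t` on `∫C_in / C_t`
  for mid-times ≥ t*; the slope is DVR with a reference input (BPnd =
  DVR − 1 reported) or V_t with an arterial input. The k2' correction term
  is omitted (reduced Logan); at late t* with typical kinetics the bias is
  small (the suite checks < 5% on forward-simulated data with k2 = 0.3
  min^-1), but it grows for slowly equilibrating tracers — a documented
  limitation.
* **Patlak-Gjedde plot** (irreversible tracers): OLS of `C_t / C_in` on
  normalized time `∫C_in / C_in` for mid-times ≥ t*; slope Ki (min^-1),
  intercept V.
* **SRTM** by basis functions: for each candidate apparent efflux rate k2a,
  the model `C_t = R1 C_ref + (k2 − R1 k2a)(C_ref ⊗ e^{−k2a t})` is linear
  and solved by least squares; the default grid is 30 log-spaced values in
  [0.01, 1] min^-1. Because a ~17%-per-step grid cannot by itself guarantee
  3% parameter recovery, the grid minimum is refined by golden-section
  search within the bracketing interval (the voxelwise path stays on the
  grid for speed, and documents that). The discrete convolution uses exact
  piecewise-linear-times-exponential quadrature on the nonuniform frame
  grid. A best k2a at the grid boundary triggers a warning rather than an
  error.
* **SUVR**: ratio of duration-weighted mean activities over a late window.
  The window is a required configuration input — no universal default is
  defensible across tracers (the pipeline default of 40-60 min suits
  FDG-like uptake patterns).

Default t* is 20 min and configurable per model; no automatic t* search is
performed (documented limitation). Voxelwise maps apply the same estimators
per voxel; voxels failing a model's preconditions are set to 0 and flagged
in a failure mask, never interpolated.

## Automated quality control

For each subject the coregistration stage yields three similarity metrics
between the static PET and the T1 resampled into PET space: Pearson
cross-correlation (CC), mutual information (MI), and feature-space entropy
(FSE, the joint-histogram entropy), computed with the registration's
histogram settings. Across subjects, each (stage, metric) cell with at least
5 values gets a Gaussian-kernel density estimate with Silverman bandwidth
`0.9 min(sd, IQR/1.34) n^{-1/5}` on a grid spanning the data ± 3 bandwidths.

How to turn "probability of observing a metric under the empirical
distribution" into a score is genuinely open; petquant uses the
lowest-density-region tail probability: `p(x)` integrates the estimated
density over `{u : f(u) ≤ f(x)}`. This is a proper p-value-like score —
the mode scores 1, far-tail values score ~0, it is monotone in the density,
and invariant to affine rescaling of the metric. Values with p below the
threshold (default 0.05, configurable) are flagged; metrics are flagged
independently with no multiple-testing correction, mirroring per-metric
review practice. Degenerate cells (zero spread) flag nothing.

Group scoring is leave-one-out: each subject is scored against the density
of the other subjects' values. This choice is forced by small-cohort
arithmetic. If the scored value is included in its own reference density,
its kernel contributes mass 1/n to the lowest-density region, and for a
tight unimodal cohort the shape of the Gaussian adds a further ~3.5% of
low-density shoulder mass, so a single gross failure among ~20 subjects is
mathematically pinned near p ≈ 0.08 and can never cross a 0.05 threshold —
the detector would be structurally blind. Leave-one-out removes the floor:
in the acceptance suite an injected 10 mm misregistration is flagged in 20
of 20 seeded repetitions. The flip side is calibration: a well-calibrated
0.05-level score flags about 21 x 3 x 0.05 ≈ 3 clean records per
21-subject, 3-metric cohort, and the suite measures ~4; per-cohort flag
counts that low *and* single-outlier sensitivity cannot coexist at a fixed
0.05 threshold, so petquant prefers sensitivity and treats flags as review
prompts, not verdicts. Users who want fewer prompts can lower the
threshold or switch `group_qc(scoring = "pooled")`, which restores the
conservative in-sample behaviour (about one flag per clean cohort) at the
cost of single-outlier blindness in small cohorts.

The same metric trio is an available extension point for PVC- and
quantification-stage QC (input vs output of the stage); only the
coregistration trio is anchored in established practice.

## The synthetic phantom

The generator exists so every stage can be validated against known ground
truth without external data. It deliberately replaces Monte-Carlo scanner
physics (scatter, randoms, attenuation, reconstruction) with a blur + noise
forward model: validation targets the pipeline's inversion properties, not
scanner realism. Consequently, passing tests demonstrate correct
implementation of coregistration, GTM/deconvolution inversion, kinetic
estimation and QC under the stated forward model — they do not demonstrate
robustness to scatter artefacts, attenuation errors, motion, or anatomical
variability, none of which the phantom emulates.

The default anatomy, on a 49 x 57 x 49 grid of 2 mm voxels with the world
origin at the grid center, comprises a cortical shell (outer ellipsoid
semi-axes 34 x 42 x 34 mm, inner scale 0.8), a deep white-matter-like
filler, a putamen-like ellipsoid (12 x 9 x 9 mm semi-axes, ~4.1 cm^3), a
smaller caudate-like ellipsoid, and a cerebellum-like reference region, all
carved from the filler; overlap between primitives is an error. The margins
keep all foreground at least 3 sigma from the grid edge for the default
6.5 mm FWHM PSF.

Each region carries one of four TAC archetypes, all starting at zero
activity: a gamma-variate reference `A t^b e^{-t/tau}` (defaults A = 4,
b = 1, tau = 15 min: ~22 kBq/mL peak near 15 min, a realistic
reference-region shape); a *ratio* archetype (scaled reference, SUVR-style)
for the FDG-like phantom; an *irreversible* archetype
`Ki ∫C_ref + V C_ref` (analytic running integral, so a Patlak plot of the
pair is exactly linear with slope Ki) for the FDOPA-like phantom, default
putamen Ki = 0.012 min^-1; and a *reversible* SRTM archetype integrated by
lsoda on a 0.01 min grid and frame-averaged, for the raclopride-like
phantom (default caudate R1 = 1, k2 = 0.3 min^-1, BPnd = 2). Region
contrast defaults (e.g. cortex/reference ratio 2 for the FDG-like tracer)
were chosen once as kinetically typical for each tracer class; the
validation conclusions do not hinge on them.

Rendering paints each frame's regional activities, blurs with the PSF, and
adds zero-mean Gaussian noise with voxel standard deviation
`noise_scale * sqrt(activity / frame_duration)` — variance proportional to
activity and inversely to frame duration, the standard first-order model of
reconstructed PET noise. The default `noise_scale = 8.5` was derived
analytically, before any test was run, so that the putamen-like region's
regional-mean SNR at the final frame is approximately 20 under the
FDOPA-like defaults; voxel-level SNR is then near 1 in late frames, which is
the realistic regime for dynamic PET. The default frame schedule is
6 x 0.5, 4 x 3, 12 x 4 min (63 min), a common dynamic protocol shape. All
generator outputs are pure functions of (spec, seed).

## Problem sizes in the validation suite

The acceptance experiments run the full-size default phantom (~137k voxels,
22 frames). Image-domain unit tests (registration properties, idSURF,
pipeline determinism) use a geometrically similar phantom scaled to a
37 x 43 x 37 grid, and the pipeline determinism experiment uses 5 subjects
— the smallest cohort that still exercises the automated QC path. These
sizes were chosen as the smallest that leave every tested contrast
comfortably above numerical noise.

## Known limitations

* No motion correction across frames, and no nonlinear or affine (9/12
  parameter) registration.
* Reduced Logan (no k2' term), no automatic t* selection, no full
  two-tissue-compartment nonlinear fitting, no metabolite or blood-volume
  correction.
* GTM assumes a spatially invariant Gaussian PSF and correct labels; label
  errors propagate directly into corrected TACs.
* The `.dft` reader supports a declared minimal dialect (`#` headers with
  optional unit/kind declarations; `start end activity` or `time activity`
  rows) — calibration headers of the full Turku format are not parsed.
* The pipeline configuration file is YAML.
* "Vertical format" output is long format (one value per row with the
  header `sub,ses,task,run,stage,region,metric,value`); the occasionally
  seen description of such tables as "wide" is a naming collision this
  package resolves in favour of long.
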