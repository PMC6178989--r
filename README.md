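# petquant

Quantitative analysis of dynamic PET, from reconstructed images to regional
kinetic parameters, for researchers who need an automated, reproducible
pipeline rather than interactive per-scan processing. petquant covers the
three core processing stages — rigid PET-to-T1 coregistration, partial-volume
correction (PVC), and tracer kinetic quantification — plus automated
group-level quality control and long-format results reporting, and ships a
synthetic dynamic-phantom generator so that the whole chain can be validated
end-to-end against known ground truth.

## What it computes

* **Coregistration**: six-parameter rigid alignment of the static
  (time-weighted average) PET to the T1, maximizing normalized mutual
  information, NMI = (H(A)+H(B)) / H(A,B), hierarchically over a Gaussian
  pyramid with an initial binary-mask stage.
* **PVC**: the geometric transfer matrix (GTM) method — solve `W t = o`
  per frame, where `W[i,j]` is the mean over region *i* of the PSF-blurred
  indicator of region *j* — and an anatomically constrained iterative
  deconvolution (`f_{k+1} = S[f_k + α(g − G f_k)]`, with `S` smoothing only
  within labels).
* **Quantification**: Logan plot (slope = DVR, BPnd = DVR − 1 with a
  reference input), Patlak–Gjedde plot (slope = Ki, min⁻¹), simplified
  reference tissue model via basis functions (R1, k2, BPnd), and SUVR
  (duration-weighted late-window ratio), in ROI and voxelwise modes, with
  reference-region or arterial (`.dft`) input.
* **QC**: per-subject CC / MI / FSE similarity metrics, scored against the
  group's kernel-density estimate; a value is flagged when its
  lowest-density-region tail probability falls below 0.05.
* **Reporting**: long-format CSVs keyed by BIDS entities
  (`sub,ses,task,run,stage,region,metric,value`) plus group descriptives.

Inputs are BIDS-organized NIfTI volumes (`sub-*/pet/*_pet.nii[.gz]` with a
frame-timing JSON sidecar, `anat/*_T1w.nii*`, label volumes as
`anat/*_dseg.nii*`). Time is minutes, activity kBq/mL internally.

## Worked example

Generate a 5-subject phantom cohort, run the participant and group levels,
and inspect the recovery of a known irreversible uptake rate:

```r
library(petquant)

root <- "phantom_bids"; out <- "phantom_out"
phantom_bids_tree(root, n_subjects = 5, tracer = "fdopa", seed = 1)

cfg <- pipeline_config(pvc = "gtm", quant = "patlak", ref_label = 5L,
                       t_star = 20)
run_participant_level(root, out, cfg)
run_group(out, cfg)
```

The same experiment is available without file I/O. A 15-subject cohort
(subjects differ by noise seed) summarizes recovery as the mean ratio of
recovered to true regional TAC integrals:

```r
co <- recovery_cohort("fdopa", n_subjects = 15, seed = 1)
co$summary
#>       region uncorrected_mean uncorrected_sd corrected_mean corrected_sd
#> 1     cortex           0.7704       0.002200         1.0011     0.003376
#> 2       deep           1.1235       0.004567         0.9995     0.005763
#> 3    putamen           0.8019       0.010659         0.9967     0.016014
#> 4    caudate           0.7712       0.015092         1.0016     0.026801
#> 5 cerebellum           0.8848       0.013696         0.9979     0.019090
co$ki_ratio
#> [1] 1.011578
```

Reading: after the 6.5 mm FWHM blur, the small bright putamen-like region
keeps only ~80% of its true TAC integral (spill-out); GTM correction with
the matched PSF restores the cohort mean to within 0.4% of truth, and the
Patlak slope fitted on the corrected curves (cerebellum-like reference,
t* = 20 min) recovers the simulated Ki = 0.012 min⁻¹ to ~1% on average —
with an across-subject spread of roughly ±9% at this noise level, which is
why the cohort mean, not a single subject, is the reported statistic.

A command-line interface mirrors BIDS-apps conventions
(`inst/cli/petquant.R <input> <output> participant|group ...`,
`inst/cli/petquant-phantom.R <output>`).

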