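# vsoptrack

In vivo MRI quantification of iron-oxide-labelled stem cells and ischaemic
lesions in longitudinal rodent brain imaging — as a tested, reusable R
pipeline exercised end to end on synthetic brain phantoms with known ground
truth.

## The problem

Stem cells labelled with very small superparamagnetic iron oxide particles
(VSOP) show up on T2\*-weighted gradient-echo MRI as few-voxel hypointense
"dots"; the ischaemic lesion of a middle cerebral artery occlusion (MCAo)
shows up on T2-weighted images as a hyperintense region. Quantifying both,
per animal and over time, takes three measurements that this package
implements for anyone analysing small-animal cell-tracking MRI:

* **ΔCSI**, the hemisphere cell-signal asymmetry: per slice,

  $$\Delta CSI = \sqrt{(SD_{contra}/mean_{contra})^2 + (SD_{aff}/mean_{aff})^2},$$

  the root-sum-of-squares of the two hemispheres' coefficients of
  variation, averaged over seven lesion-spanning T2\* slices. Scattered
  hypointense cell deposits inflate the affected hemisphere's CV, so ΔCSI
  rises with delivered cell number.

* **Infarct volumetry with interslice-gap interpolation**: per-slice lesion
  areas × slice thickness, plus each gap × the mean area of its two
  neighbour slices; reported as a percentage of the brain volume computed
  the same way, and longitudinally as the residual infarct (9 d volume as a
  percentage of the same animal's 48 h volume).

* **A T2\* speckle re-analysis** isolating cell-derived voxels when tissue
  transformation muddies the late-timepoint signal: bias-field correction,
  brain extraction, mean-1000 normalization and rigid inter-session
  alignment, then per volume the absolute median-filter residual, local
  Wiener denoising, thresholding at the affected hemisphere's mean + 2 SD,
  and a histogram split that keeps only the hypointense class. Voxel counts
  and connected clusters are compared across timepoints; unmatched clusters
  flag appeared/disappeared signals, i.e. cell migration.

Because the in vivo dataset behind these methods exists only as summary
tables, the package ships a synthetic phantom generator
(`generate_phantom()`, `generate_phantom_pair()`) that emulates the
acquisition geometry (14 × 11 mm field of view, 20 slices of 0.8 mm with a
0.2 mm gap), an ellipsoidal brain and lesion, planted speckles with exact
ground-truth coordinates, multiplicative bias fields, noise, and planted
inter-session misalignment — so every stage is testable without any
download.

## Worked example

```r
library(vsoptrack)

cfg <- phantom_config(seed = 7)        # default geometry, 300 planted speckles
ph  <- generate_phantom(cfg)

mask   <- extract_brain(ph$t2)
t2     <- normalize_mean(correct_bias(ph$t2, mask)$vol, mask)
t2star <- normalize_mean(correct_bias(ph$t2star, mask)$vol, mask)

animal_delta_csi(t2star, mask, lesion_mask = ph$truth$lesion_mask)
#> <delta_csi_result> mean dCSI 0.06219 (SD 0.00713) over 7 slices

infarct_volumetry(t2, mask)
#> <infarct_volume_result> lesion 65.41 mm^3 / brain 909.10 mm^3 = 7.19%

ph$truth$lesion_volume_mm3             # analytic 4/3*pi*abc ground truth
#> [1] 62.83185

build_speckle_map(t2star, mask)
#> <speckle_map> 289 hypointense voxels in 289 clusters (threshold 99.866), timepoint 48h
```

The mean ΔCSI of 0.062 says the affected hemisphere's coefficient of
variation is three times the contralateral noise floor — a mid-dose cell
load. The recovered lesion volume (65.4 mm³, 7.19% of brain) is within
4.1% of the analytic ellipsoid volume; 289 of the 300 planted speckles are
recovered with zero false positives.

`run_study()` drives a whole synthetic cohort (four dose groups, optional
second timepoint per animal) through the full chain and writes per-animal
CSV tables, group median/IQR/range summaries, and exact Mann-Whitney
comparisons against the control group. The numbered scripts under
`analysis/` run the same workflow as a narrative: `01_simulate_cohort.R`
writes NIfTI phantoms, `02_dose_response_dcsi.R` the ΔCSI dose-response
tables, `03_infarct_volumetry.R` the infarct and residual-infarct tables,
`04_longitudinal_speckles.R` the registered two-timepoint voxel counts and
the migration demonstration.

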