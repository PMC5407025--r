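---
title: "Quantifying iron-labelled stem cells and infarcts in rodent brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying iron-labelled stem cells and infarcts in rodent brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsoptrack)
```

## The measurement problem

Stem cells labelled with very small superparamagnetic iron oxide particles
(VSOP) disturb the local magnetic field and appear as few-voxel hypointense
"dots" on T2\*-weighted gradient-echo MRI. In a rodent stroke model
(middle cerebral artery occlusion, MCAo; right-sided, so the right
hemisphere is the *affected* one), three quantities track the fate of
intra-arterially delivered cells and of the ischaemic lesion:

1. **ΔCSI**, a hemisphere asymmetry statistic of the T2\* signal. For each
   analysed slice, both hemispheres serve as regions of interest and

   $$\Delta CSI \;=\; \sqrt{\left(\frac{SD_{contra}}{mean_{contra}}\right)^{2} +
   \left(\frac{SD_{aff}}{mean_{aff}}\right)^{2}},$$

   the root-sum-of-squares of the two coefficients of variation, averaged
   over seven lesion-spanning slices. Scattered hypointense deposits
   inflate the affected hemisphere's CV, so ΔCSI grows with the delivered
   cell load. It is dimensionless and invariant under any positive
   rescaling of the intensities, which makes it robust to scanner gain.

2. **Infarct volume** from T2-weighted hyperintensity: per-slice lesion
   areas are multiplied by the acquired slice thickness, each interslice
   gap contributes the gap width times the mean area of its two neighbour
   slices, and everything is summed. The result is expressed as a
   percentage of the total brain volume computed the same way, and the
   9-day volume as a percentage of the same animal's 48-hour volume
   (*residual infarct*).

3. **Cell-derived voxel counts** from a T2\* re-analysis that separates
   iron-laden cells from evolving tissue damage: bias-field correction,
   brain extraction, normalization of the brain mean to 1000, rigid
   alignment of the later session, then — per volume — the absolute
   residual against a median-filtered copy, local (Wiener) noise
   reduction, thresholding at the affected hemisphere's mean + 2 SD, and a
   histogram split of the surviving voxels' original intensities that
   keeps only the hypointense class. Voxel counts and their connected
   clusters are compared across timepoints; clusters without a partner
   within a small centroid distance are flagged as appeared or
   disappeared — the signature of cell migration.

Because the underlying in vivo dataset exists only as published summary
tables, the package ships a synthetic phantom generator with exact ground
truth, and every claim the package makes about its own accuracy is a
measurement on those phantoms.

## The phantom: what it emulates and what it does not

`phantom_config()` builds a coronal rodent-brain acquisition: a
14 × 11 mm in-plane field of view on a 128 × 104 grid and 20 slices of
0.8 mm thickness with a 0.2 mm gap. The brain is an ellipsoid
(semi-axes 5.6 × 4.4 × 8.8 mm) of homogeneous tissue; an ellipsoidal
lesion (default semi-axes 2 × 2.5 × 3 mm, analytic volume
$\tfrac{4}{3}\pi abc = 62.8\,\mathrm{mm^3}$, about 6–7% of the brain) sits
in the right hemisphere and is +50% hyperintense on T2. Cell deposits are
planted as single-voxel (or 6-neighbour "cross") speckles at a minimum
mutual separation, in and around the lesion, each reducing the T2\*
intensity by `speckle_contrast` (default 0.5); a configurable fraction is
made hyperintense instead, as confounders for the histogram step. A smooth
random polynomial field (mean exactly 1 over the brain, peak deviation
exactly `bias_amplitude`, default 0.1) multiplies the volume, then
additive Gaussian noise (default SD 2% of tissue intensity) is drawn
independently per contrast and session. The second timepoint re-renders
the same geometry, optionally with migrated speckles, moves it by a rigid
transform, and receives a fresh bias field and noise draw.

Deliberate idealizations, and what they mean for interpreting green tests:

* **No MR physics.** Intensities are phenomenological; nothing is said
  about echo times, relaxivities, or iron load per cell. Speckle contrast
  is a free parameter, not calibrated to VSOP concentration, so detection
  rates on phantoms do not translate into cells-per-voxel claims.
* **Gaussian noise, not Rician.** At the phantom's signal-to-noise ratio
  the difference is negligible for threshold logic; a Rician option
  (`noise_model = "rician"`) exists for sensitivity checks.
* **Binary structure.** Lesion and speckles have sharp edges and no
  partial-volume ramp; tissue is homogeneous. Real T2/T2\* anatomy has
  texture that would raise both hemispheres' CVs and the speckle
  threshold. ΔCSI's contrast between groups is therefore cleaner here
  than in vivo.
* **Single-voxel speckles are fragile under sub-voxel resampling.**
  Trilinear interpolation spreads a one-voxel deposit over its
  neighbours, diluting contrast — a real partial-volume effect that
  multi-voxel in vivo "dots" largely escape. The longitudinal phantoms
  therefore use the cross footprint, and the default planted
  inter-session misalignment is an in-plane shift of (2, 1, 0) voxels.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `lesion_t2_factor` | 1.5 | — | T2 lesion hyperintensity; drives segmentation |
| `n_speckles` | 300 | count | planted deposits; dose analogue ({0, 50, 300, 1000} in the dose-response study) |
| `speckle_contrast` | 0.5 | fraction | per-voxel T2\* signal drop |
| `bias_amplitude` | 0.1 | fraction | peak multiplicative inhomogeneity |
| `noise_sigma` | 0.02 | fraction of tissue | additive noise SD |
| `poly_order` (correction) | 3 | — | bias-fit polynomial order |
| `k_sd` (segmentation, threshold) | 2 | SD | contralateral / hemisphere threshold multiplier |
| `median_kernel_vox`, `wiener_window_vox` | 3 | voxels | filter footprints (3D) |
| `erode_mask_vox` | 1 | voxels | hemisphere-mask erosion before thresholding |
| `match_tol_vox` | 3 | voxels | cluster centroid matching tolerance |

## Numerical and design choices

**ΔCSI reading.** The asymmetry index is defined as the root-sum-of-squares
of the two hemispheres' CVs; only this reading yields a single nonnegative
index that grows with unilateral signal heterogeneity. Sample SD
(divisor n − 1) is used in every ROI statistic. Slices default to the seven
centred on the lesion's through-plane centroid — anatomical landmarks are
not reproducible in phantoms — and can be overridden by explicit indices.
Whether ΔCSI is computed before or after normalization is immaterial by
scale invariance (asserted to 1e-9 in the tests), but bias-field
correction *is* material: the field inflates both CVs and its seed-to-seed
variability would otherwise swamp the low-dose effect, so ΔCSI is computed
on corrected volumes.

**Hemisphere split.** The midline is the sagittal index of the brain-mask
centroid; voxels exactly on the plane count as contralateral, a
conservative tie-break that never inflates the affected ROI.

**Bias correction.** The multiplicative field is fitted in the log domain
over a 3D polynomial basis (order 3 by default) restricted to the brain
mask, with two reweighting passes that drop voxels whose log-residual
exceeds 2.5 scaled MADs — without this the fit absorbs part of the
lesion's +50% intensity and the "correction" worsens tissue uniformity.
The estimated field is rescaled so the brain-mean is preserved exactly;
voxels outside the mask are untouched.

**Normalization region.** The brain-mask mean is set to 1000 (a
whole-grid option exists): air dominates the whole-grid mean and would
make the normalization depend on the field of view.

**Registration.** Six degrees of freedom, normalized cross-correlation,
initialized at the integer-voxel FFT cross-correlation peak and refined by
Nelder–Mead at a 2× in-plane subsampled and then the full resolution.
Trilinear interpolation for intensities, nearest-neighbour (0.5 threshold)
for masks. Measured recovery on default phantoms: within 0.15 voxel and
0.1° for planted |rotations| ≤ 10° and |translations| ≤ 5 voxels. If the
search cannot beat the identity's similarity, the identity is returned.

**Speckle chain.** Filters run in 3D with reflective boundaries. The
threshold statistics use the *affected* hemisphere (the literal reading
for a right-sided occlusion; a contralateral-referenced switch exists),
with a strict `>` at mean + 2 sample SD. The hemisphere mask is eroded by
one voxel first: voxels adjacent to background carry large partial-volume
residuals that are edges, not cells. The hypo/hyper split maximizes
between-class variance over a 256-bin histogram; because a two-class split
of an effectively unimodal set is arbitrary (it would discard half of a
pure hypointense population), the split is only trusted when the
between-class variance explains ≥ 80% of the total (η² ≥ 0.8, comfortably
above the ≈ 0.64–0.75 of unimodal samples). Unimodal sets are classified
wholesale: kept if their mean is below 95% of the brain mean (clearly
hypointense), discarded otherwise — this also keeps the false-positive
count on speckle-free phantoms at zero, where the mean + 2 SD threshold
alone would pass ≈ 2% of any near-Gaussian field.

**Cluster bookkeeping.** 26-connectivity; greedy nearest-centroid matching
within 3 voxels. `migrate_speckles()` re-plants displaced deposits only at
sites that keep the phantom's minimum speckle separation, so a planted
migration is unambiguous: with separation ≥ 8 voxels and a displacement
larger than the matching tolerance, exactly one appeared and one
disappeared cluster follow by geometry, for any seed.

**Degenerate inputs.** Empty segmentations warn and return empty masks
(legitimate for controls); an all-skipped slice set, nonpositive ROI
means, empty groups, and a zero 48-hour baseline volume are errors.

## Problem sizes

Unit tests run mostly on a quarter-scale phantom (64 × 52 × 12 at the
same anatomy proportions; sub-second per phantom). The end-to-end checks
use the full default geometry: 10 seeds for volume recovery, 8 animals per
group across the four dose levels for the ΔCSI ordering and Mann–Whitney
comparisons, 10 registered two-timepoint pairs for longitudinal count
stability, and 10 planted transforms for registration recovery. A
complete `run_study()` over a 20-animal cohort takes a few minutes on one
core.

## A worked miniature

```{r mini, eval = TRUE}
cfg <- phantom_config(grid_shape = c(64L, 52L, 12L),
                      voxel_size_mm = c(14 / 64, 11 / 52, 1),
                      brain_axes_mm = c(5.6, 4.4, 4.8),
                      lesion_axes_mm = c(1.6, 2, 2.4),
                      lesion_center_mm = c(2.6, 0.4, 0),
                      n_speckles = 60L, seed = 1L)
ph <- generate_phantom(cfg)
mask <- extract_brain(ph$t2)
t2 <- normalize_mean(correct_bias(ph$t2, mask)$vol, mask)
t2star <- normalize_mean(correct_bias(ph$t2star, mask)$vol, mask)

animal_delta_csi(t2star, mask, lesion_mask = ph$truth$lesion_mask)
infarct_volumetry(t2, mask)
build_speckle_map(t2star, mask)
ph$truth$lesion_volume_mm3
```

## Known limitations

* The lesion segmentation is an operator-free surrogate (contralateral
  mean + 2 SD threshold) for the manual hyperintensity tracing done in
  practice; externally drawn lesion masks are accepted wherever a lesion
  mask is.
* Voxel counts are never converted to absolute cell numbers; no
  voxels-per-cell calibration exists.
* No oedema or hemisphere-swelling correction is applied to the
  volumetry.
* The phantom's lesion geometry is static between sessions, so the
  residual infarct on phantom pairs is ~100% by construction; the
  residual statistic is exercised as bookkeeping (and by its arithmetic
  contract), not as lesion-evolution biology.
* Registration assumes same-animal longitudinal geometry (small rigid
  motion); it is not a general-purpose inter-subject tool.
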