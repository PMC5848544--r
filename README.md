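# histomri

Tools for relating quantitative *post mortem* brain MRI to stained
histology sections. The package is aimed at neuroimaging and
neuropathology groups who scan fixed whole brains or spinal cord at high
field, photograph the coronal slices and excised tissue blocks during
cut-up, digitise immunohistochemically stained sections, and want
voxel-matched, quantitative comparisons between MR parameter maps and
stained area fractions.

## What it does

**Quantitative MR parameter maps.** Voxel-wise estimators for the
standard *post mortem* protocols:

* `trufi_rms_combine()` — root-mean-square combination of phase-cycled
  balanced-SSFP structural scans;
* `fit_t2_loglinear()`, `fit_t2star_map()` — signal-weighted
  pseudoinverse of the linearised decay `ln S = ln S0 − TE/T2`, with an
  R2\* companion map;
* `fit_t1_ir()` — non-linear magnitude inversion-recovery fit
  `S(TI) = |a + b·exp(−TI/T1)|` with a multi-start over the polarity
  ambiguity;
* `fit_dti_loglinear()` — log-linear diffusion tensor fit with FA, MD
  and principal-direction maps;
* `qsm_chain()` — susceptibility mapping: multi-echo field-map fit
  (temporal or Laplacian `laplacian_unwrap()` unwrapping), V-SHARP
  background-field removal (`vsharp_filter()`), and thresholded
  k-space dipole inversion (`dipole_invert()`) with the standard
  point-spread amplitude correction.

**Stain quantification.** Colour deconvolution in Beer–Lambert optical
densities (`rgb_to_od()`, `deconvolve()`, calibration with
`calibrate_stain_vectors()`), positive-pixel classification into
unstained / negative / weak / medium / strong (`classify_pixels()`)
inside polygonal include/exclude annotations, stained area fractions
(`stained_area_fraction()`) and markup rendering (`render_markup()`).

**Histology-to-MRI co-registration.** The staged photograph-mediated
chain: blue-background keying (`segment_background()`), NMI-driven
block-face insertion informed by the cut-out slice photograph
(`insert_block_face()`), anti-aliased histology subsampling, MIND
descriptor affine and deformable registration to the block face
(`compute_mind()`, `register_affine()`, `register_deformable()`),
curvilinear-surface resampling of the MR volume
(`fit_curvilinear_surface()`, `resample_along_surface()`) with
boundary-based registration on the grey/white interface
(`bbr_register()`), composed into a single histology-to-voxel map
(`compose_chain()`, `map_histology_to_mr()`).

**ROI statistics.** Per-voxel ROI summaries (`extract_roi_values()`),
Welch/pooled two-tailed t tests (`two_sample_ttest()`) that work
identically from raw values or printed (mean, SD, n) summaries, and a
combined MRI + histology region-comparison report
(`build_comparison_report()`).

**Phantoms.** Every input has a seeded generator with attached ground
truth (`make_slice_pair()`, `make_histology_phantom()`,
`make_signal_stack()`, `make_registration_phantom()`), so the whole
pipeline is testable end to end without any data download.

## Worked example

Recompute the region comparison between a degenerating white-matter
tract and normal-appearing white matter from per-voxel summary
statistics (FA 0.17 ± 0.03 in 276 voxels vs 0.19 ± 0.07 in 269):

```r
library(histomri)
a <- roi_summary(0.17, 0.03, 276, modality = "fa", roi = "lateral CST")
b <- roi_summary(0.19, 0.07, 269, modality = "fa", roi = "NAWM")
two_sample_ttest(a, b)
#> t = -4.316, df = 361.3, two-tailed p = 2.06e-05 (welch)
```

Run the full registration chain on the seeded phantom and inspect the
landmark error:

```r
ph  <- make_registration_phantom(42)
fit <- run_registration_chain(ph)
fit
#> chain_fit:
#>   insertion: 7.00 deg, t=(57.00, 48.00), NMI 2.000
#>   affine scale: 0.8878
#>   deformable: min Jacobian 0.454
#>   landmark TRE: mean 0.651, max 1.047 voxels (n=25)
```

The insertion pose is recovered to a few thousandths of a degree, the
histology affine recovers the simulated 0.9 paraffin shrinkage, and the
25 seeded landmarks land within about half a voxel of their true MR
positions on average.

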