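---
title: "Models and methods behind histomri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind histomri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole fixed brains and spinal cord can be scanned at high field for days,
yielding quantitative maps — T1, T2, T2\*, diffusion tensor metrics,
magnetic susceptibility — at sub-millimetre resolution. The same tissue is
then cut into slices, blocks are excised for histology, and sections are
stained for myelin, glia, iron or pathological protein aggregates. The
scientific payoff comes from comparing the two *in the same voxels*, which
requires (i) trustworthy parameter-map estimation, (ii) quantitative stain
read-outs, (iii) a geometric chain carrying a 2-D histology section into
the 3-D MR volume, and (iv) region-level statistics. `histomri`
implements all four, plus seeded phantom generators so every stage is
validated against known ground truth.

# Quantitative map fitting

**Phase-cycled structural combination.** Balanced-SSFP acquisitions show
banding that moves with the phase-cycling increment; the root-mean-square
across cycles `sqrt(mean(S_i^2))` suppresses it. The phantom for this is a
common anatomy multiplied by a shifted banding profile per cycle; the test
checks that the combined image has lower spatial coefficient of variation
than any single cycle.

**T2 and T2\*.** The decay `S(TE) = S0 exp(-TE/T2)` is linear in the log,
so the fit is a per-voxel weighted straight line. The weights default to
the measured magnitude: after a log transform, additive noise of constant
variance becomes relative, and weighting by signal restores approximately
uniform variance (the common first-order correction for log-transformed
Rician data; squared-signal weighting is a documented alternative via the
`weighting` argument). Voxels with non-positive signal or non-negative
slope are masked invalid rather than reported. TE is in ms throughout, so
R2\* = 1/T2\* is per ms.

**T1.** Turbo-spin-echo inversion recovery with TR comparable to the
longest TI leaves relaxation incomplete, so a fixed-form
`S0(1 - 2exp(-TI/T1))` model would be biased. We fit the generic
3-parameter magnitude model `|a + b exp(-TI/T1)|`, which absorbs
saturation and inversion-efficiency effects. Magnitude data lose the sign
of the recovery curve, creating the classic polarity ambiguity around the
zero crossing; the fitter restores every candidate polarity (negating the
first k sorted samples for k = 0..n), solves the then-linear (a, b)
subproblem exactly for each trial T1, optimises T1 by golden-section
search in (1, 10000] ms, and keeps the lowest-residual candidate. This is
deterministic and has no starting-value sensitivity. Both plain magnitude
and sign-restored inputs are accepted — restoration happens internally.

**Diffusion tensor.** Ordinary least squares on
`ln(S/S0) = -b g' D g` with at least one b = 0 volume and six
non-collinear directions (the design matrix must reach rank 6). FA and MD
come from the eigenvalues, clamped at zero with a diagnostic count when
noise drives them negative. Eigenvalues are reported descending; the
principal eigenvector's sign is fixed (non-negative third component,
ties broken on the second) so repeated runs are bit-identical. The
bespoke steady-state diffusion signal model used for very long *post
mortem* acquisitions is out of scope; the fit operates on standard
diffusion-weighted stacks.

# The susceptibility chain

Gradient-echo phase evolves as `phi(TE) = phi0 + 2 pi df TE` with
`df` proportional to the local field. The chain is: field-map fit, then
background-field removal, then dipole inversion.

**Unwrapping.** Two routes are provided. `laplacian_unwrap()` solves
`lap psi = cos(phi) lap sin(phi) - sin(phi) lap cos(phi)` spectrally on a
mirror-extended domain (even symmetry gives Neumann behaviour without a
mask). Spectral rather than finite-difference Laplacians matter: the
discrete 6-neighbour operator attenuates steep ramps by sin(a)/a per
sample step, a 0.25 rad bias on a six-pi ramp at 48 samples, while the
spectral operator recovers the same ramp to ~0.002 rad. The additive
constant lost by the Poisson solve is restored by circular-mean matching
against the wrapped input. For multi-echo data the default in
`qsm_chain()` is *temporal* unwrapping — per voxel, successive echo
differences are wrapped into (-pi, pi] and accumulated — which is exact
whenever inter-echo phase steps stay below pi, as they do for the
protocol's 6.6 ms spacing at tissue field strengths. Per-echo spatial
unwrapping remains available (`unwrap = "laplacian"`, needed for
single-echo data); on the validation phantom its smoothing of the steep
phase rim around the susceptibility sphere costs about 20 % of the
sphere's recovered amplitude, which is why it is not the multi-echo
default.

**V-SHARP.** The spherical-mean-value filter `(delta - S_r) * B`
annihilates any field harmonic within radius r of each voxel — i.e. all
background generated by sources outside the mask. The radius shrinks
stepwise (default 6..1 voxels) toward the mask edge so less tissue is
lost; the mask eroded by the largest radius is returned. The remaining
`(1 - S)` deconvolution uses the *largest*-radius kernel — the one
actually applied over the mask interior — with a truncated-SVD threshold
of 0.05. Deconvolving with the smallest radius instead truncates most of
the low-frequency tissue field (its `1 - S` transfer function is near
zero over a wide low-k band) and destroys the inversion.

**Dipole inversion.** Thresholded k-space division with
`D(k) = 1/3 - kz^2/|k|^2` (B0 along the third array axis, `D(0) = 0`) and
threshold 0.19. Plain TKD is known to underestimate susceptibility
because modes near the dipole zero cone are replaced by their floored
values; the standard remedy, applied by default, is the point-spread
amplitude correction: the reconstruction PSF's central value is
`mean(D * D_inv)` over k-space, and the map is divided by it (a factor
of about 1.29 at threshold 0.19). On the 48-cube sphere phantom direct
forward–inverse recovery is then within a percent; through the full
chain the sphere median lands about 10 % low, dominated by V-SHARP's
unavoidable removal of some low-frequency tissue field.

# Stain quantification

Brightfield absorption follows Beer–Lambert: `OD_c = -log10(I_c/I0_c)`
per channel, and a pixel's OD vector is the concentration-weighted sum of
unit stain vectors. Deconvolution inverts the completed 3x3 system
exactly per pixel; with two stains the third column is the unit vector
orthogonal to both (sign-fixed), and with one stain an orthonormal
completion is used. Negative concentrations are clamped at zero and the
clamped fraction reported — with real noise a few percent is normal,
more suggests mis-calibrated vectors.

Because the reference analysis software's calibrated thresholds and
vectors are proprietary and unpublished, both are explicit inputs here:
defaults are the published haematoxylin/DAB vectors, and
`threshold_stability()` supports the recipe of checking a candidate
threshold across ten or more structurally distinct regions before
adopting it. Classification bins are half-open and lower-inclusive
(`[t_weak, t_medium)` etc.) so boundary behaviour is deterministic;
whether the "unstained" cutoff tests summed OD or the positive channel
alone is configurable (`mode`), positive-channel being the default.
Polygon annotations rasterise with even-odd fill and pixel-centre
inclusion on the 0-based grid, and excluded pixels never enter numerator
or denominator of the stained area fraction.

# The registration chain

Coordinates are 0-based (row, col) pixel centres everywhere; transforms
map *source to target* points, and images are always resampled by a
single pull-back interpolation of the composite map — no stage resamples
twice.

**Stage 1 — keying.** Photographs are taken on a saturated blue board;
foreground is chroma distance to the key colour above 0.25 (units of
[0,1] RGB), closed morphologically and reduced to the largest connected
component, holes preserved.

**Stage 2 — block insertion.** The excised block photograph is placed
into the intact-slice photograph by maximising NMI (64 foreground-only
bins). The cut-out slice photograph supplies the decisive constraint: the
candidate centre region is the intact-minus-cutout foreground difference,
dilated by 6 px — the excision hole — which prevents the spurious
insertions a whole-slice search invites. The coarse search is exhaustive
(rotation -180..178 degrees in 2 degree steps by default, flips excluded
since blocks are photographed face-up; translation stride 4 px on a
2x-decimated block) and Nelder-Mead refines continuously. On phantoms the
pose is recovered to millidegrees because the global NMI optimum is
sharp.

**Stage 3 — histology to block face.** Digitised sections are
Gaussian-prefiltered and block-mean downsampled to photograph resolution.
Cross-modality similarity uses MIND: for each pixel, patch distances to
six offsets (4-neighbourhood plus two diagonals, 3x3 Gaussian patches
with sigma 0.5 px) are turned into `exp(-SSD/V)` with V the mean axial
patch distance floored at 1e-6 of the squared dynamic range (so constant
regions stay defined), normalised to per-pixel maximum 1. This gives
exact invariance to affine intensity maps and robustness to contrast
inversion — both verified properties. The affine stage optimises 6
parameters (angle, two log scales, shear, translation) by Nelder-Mead
over a 2-level pyramid with a simplex restart at the optimum (collapsed
simplexes otherwise cost ~1 % scale accuracy); the determinant is
positive by construction. Evaluating the cost inside the tissue
foreground avoids a small scale bias from the padded border of the warped
moving image. The deformable stage is multichannel demons on the MIND
channels: force `sum_k (F_k - M_k) grad M_k` normalised by
`sum_k |grad M_k|^2 + alpha^2 (F_k - M_k)^2`, fluid smoothing sigma 2 px
on the update, diffusion smoothing sigma 1 px on the field, updates
capped at 1.5 px, 3-level pyramid, with the best field kept and early
stop after three consecutive distance increases. The minimum Jacobian
determinant is reported; on all passing fixtures it stays positive.

**Stage 4 — photo into the volume.** The physical knife cut need not be
planar, so the MR volume is resampled along a curvilinear surface: a base
plane plus a height field of normal offsets (bounded at ±5 voxels),
parameterised on a coarse node grid (default 5x5) and bilinearly
interpolated. Tissue segmentation of the photograph is deterministic
3-class 1-D k-means (quantile initialisation) over the whole slice — the
background mode anchors the darkest class — with a gap-to-within-SD
ratio below 3 rejected as unimodal; the grey/white interface is the
0.5-contour of the smoothed WM indicator, each polyline oriented so
normals point into white matter. The BBR cost is the mean tanh-saturated
signed contrast sampled ±1 px along boundary normals (scale set by the
slice MAD; polarity configurable for inverted contrasts). Surface
offsets are optimised by BFGS with a smoothness penalty on node
differences, alternating (default twice) with in-plane rigid BBR
refinement, since the spec of the physical setup does not say whether
pose and surface should be joint — alternation is the artifact's choice
and converges in two rounds on all phantoms.

**Stage 5 — composition.** Chain steps expose forward and inverse point
maps (displacement steps invert numerically by fixed-point iteration,
residual ~1e-12 on smooth fields); `map_histology_to_mr()` pulls every
slice-grid pixel back through all inverses and samples the histology
once. `target_registration_error()` evaluates seeded landmarks through
the forward chain against their true voxel coordinates.

# ROI statistics

`two_sample_ttest()` computes the two-tailed test from (mean, SD, n) —
identically whether a sample carries raw voxel values or only printed
summaries, which is what makes published tables recomputable. Welch is
the default (the variance ratios in the motivating comparison differ by
factors of 2–5); pooled is available, and on the motivating data both
variants give p < 0.001 for all four MR modalities, so the conclusion is
variant-robust. Histology rows in `build_comparison_report()` never
receive a test: one stained section per marker admits no within-region
variance estimate, and the NA columns make that explicit rather than
inviting a spurious test.

# What the phantoms emulate — and what they do not

The photograph phantoms have a grey-matter band / white-matter core
layout with smooth seeded texture: enough structure for NMI, MIND and
BBR to have signal, which white noise would not provide. The block
photograph is the intact scene resampled on the posed block grid, so the
insertion ground truth is exact by construction; histology is derived
from the block face by a known affine shrinkage (0.9, emulating paraffin
processing), a known smooth positive-Jacobian deformation (3–5 px,
emulating sectioning distortion) and a monotone contrast inversion
(emulating the modality gap). Stained sections mix known concentration
fields through Beer–Lambert optics. MR stacks evaluate the exact forward
models at the protocol parameter lists (TI 60/120/240/480/935 ms; TE
25–76 ms spin echo, 2–35 ms gradient echo) with optional Rician noise
(Gaussian real/imaginary channels); the susceptibility phantom convolves
a 0.1 ppm sphere with the unit dipole kernel at 7 T scaling.

None of this reproduces real anatomy, scanner artefacts (bias fields,
Gibbs ringing, motion), genuine histological tears and folds beyond the
simple simulated ones, perspective or scale distortion in photographs
(assumed orthographic and uniform — the acquisition geometry of real
cut-up photography is not standardised), or staining batch variability.
Passing phantoms therefore demonstrates correctness of the estimators
and the geometry under the stated models, not field performance on
degraded data.

# Problem sizes and determinism

Validation runs use 144^2 x 24 volumes with 144^2 photographs and 56^2
blocks for the chain, 64-cube susceptibility phantoms, and 500-replicate
noise simulations — sizes chosen so the full suite exercises every code
path in a few minutes while leaving all tolerances comfortably met; all
estimators are resolution-independent in their contracts. Every
generator and optimiser is deterministic given its seed and schedule;
repeated runs are bit-identical, which the suite asserts.

# Known limitations

* The affine/deformable split inside the chain is not separately
  identified — only their composite is; the shrinkage criterion is
  therefore validated on a dedicated affine-only phantom.
* V-SHARP removes some genuine low-frequency tissue field; the PSF
  correction compensates TKD's own bias but not this loss.
* The curvilinear surface is single-valued over the base plane; strongly
  folded cuts are out of scope.
* Whole-slide images are handled at a single resolution level; 0.5
  micron full-pyramid tiling is out of scope.
* `insert_block_face()` assumes the block was photographed face-up
  (no reflections in the search space).
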