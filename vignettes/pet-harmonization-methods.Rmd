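---
title: "Resolution harmonization of multi-scanner brain PET: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolution harmonization of multi-scanner brain PET: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petharm)
```

## The problem

Quantitative FDG-PET brain studies that pool data from several imaging
centers inherit a scanner effect: reconstructed images from different
scanner models have different effective spatial resolutions (roughly
4.5–6 mm FWHM for the hardware generations commonly found in retrospective
archives). Unless resolutions are matched, voxelwise and regional
comparisons confound biology with hardware. The classical remedy is to scan
a physical brain phantom on every scanner and derive a scanner-specific
smoothing filter; in retrospective studies those phantom scans usually do
not exist.

`petharm` implements a data-driven alternative that needs only the study
images themselves. Given two sets of spatially and intensity normalized
brain volumes — a *reference* set whose resolution is the coarsest (or which
has been smoothed to a chosen target resolution) and a *test* set — it
estimates the anisotropic Gaussian filter

$$\Theta^\* = (\mathrm{FWHM}_{XY},\, \mathrm{FWHM}_Z)
  = \arg\max_{\Theta}\; \mathrm{SSIM}\!\left(I_{\mathrm{ref}},\,
  G(\Theta) * I_{\mathrm{test}}\right)$$

where $I_{\mathrm{ref}}$ and $I_{\mathrm{test}}$ are the cohort-average
images, $G(\Theta)$ is a separable 3D Gaussian with one in-plane width
(shared by both transaxial axes) and one axial width, and SSIM is the mean
structural similarity index over the volume.

## Why cohort averages

Two scanners' image sets differ through four mechanisms: intrinsic
metabolic differences between subjects, image noise, imperfect spatial
normalization, and spatial resolution. Averaging `n` normalized images
suppresses the first two by roughly $1/\sqrt{n}$, and residual
misregistration acts on the average like a small extra blur that is
comparable between the two sets. What remains as the dominant difference
between the two averages is resolution — precisely the quantity the filter
should absorb. The method is therefore intended for group-average images;
single-subject estimation is possible mechanically but is noise-limited and
not a supported use.

## Objective and optimizer

SSIM is computed with Gaussian-weighted local statistics (window sigma 1.5
voxels, 11×11×11 support, $k_1 = 0.01$, $k_2 = 0.03$), the standard
volumetric convention. Two package-level choices deserve note:

* **Dynamic range.** The stabilizers use $L = \max(I_{\mathrm{ref}}) -
  \min(I_{\mathrm{ref}})$ by default, i.e. the *reference* range. Taking
  $L$ from the pair would let the objective drift as the test image is
  smoothed during optimization; fixing it to the reference keeps the
  objective a function of $\Theta$ alone. An explicit `dynamic_range`
  restores exact symmetry when wanted.
* **Whole-volume average.** The SSIM map is averaged over all voxels,
  including background, matching a plain volumetric `ssim` call; an
  optional mask argument restricts the average when a brain mask is
  preferred.

The search runs in two stages over the box $[0, U]^2$: an exhaustive grid
at 0.5 mm spacing (fine enough to resolve the ≈1 mm uncertainty scale the
SSIM landscape exhibits), then Nelder–Mead refinement started at the grid
optimum with parameters clamped to the box. A derivative-free second stage
is deliberate: the objective is evaluated through discrete convolution and
is not smooth at the $10^{-8}$ level, which defeats finite-difference
gradients. Refinement is accepted only if it does not decrease the
objective, so the reported optimum is never worse than the best grid point.
Ties on flat plateaus break toward the least smoothing (smallest
$\mathrm{FWHM}_{XY}$, then smallest $\mathrm{FWHM}_Z$). The upper bound $U$
follows the target resolution — 6, 10 and 16 mm for targets of 6, 8 and
10 mm — wide enough not to bias the estimate; an optimum landing on the
bound is flagged.

On noiseless planted problems the SSIM surface is unimodal with a single
4-neighborhood maximum, and its level curves near the optimum form an
ellipse tilted against the axes: the two filter widths are anti-correlated,
an increase in one being partially compensated by a decrease in the other.
The unimodality property is asserted in the test suite; the tilted ellipse
can be inspected on any exported `ssim_surface()` CSV.

## Quadratic resolution arithmetic

Sequential Gaussian blurs combine in quadrature. A scanner of effective
resolution $F_s$ reaches a coarser target $F_t$ with a filter of width
$F_f = \sqrt{F_t^2 - F_s^2}$, applied separately per direction with
direction-specific scanner values. When $F_t \le F_s$ no filter can help;
`required_filter()` clamps to 0 with a warning rather than erroring,
because validation designs legitimately include scanners already at the
target. This rule provides both the reference-preparation filter and the
ground truth against which data-driven estimates are scored.

## Gaussian filtering: numerical choices

Filtering is separable 1D convolution (Rcpp) with per-axis sigma
`fwhm_to_sigma(fwhm) / spacing` in voxels:

* **Boundary**: replicate-nearest padding, consistent between the filter
  and the SSIM local-statistics windows. Brain support sits well inside the
  field of view, so the choice is second-order, but it is fixed and
  documented for reproducibility.
* **Truncation**: kernels are cut at 4 sigma per side (truncation error
  below $10^{-4}$); sigma below $10^{-4}$ voxels is treated as identity.
* **In-plane isotropy**: one FWHM drives both XY axes; the optimization is
  intentionally two-dimensional.
* Total intensity is conserved to $10^{-6}$ relative for interior support,
  and the semigroup property
  $G(b) * G(a) \approx G(\sqrt{a^2+b^2})$ holds to $10^{-4}$ of the image
  maximum on smooth inputs — both are regression-tested, as is the measured
  impulse-response FWHM (within 0.25 mm of nominal).

Voxel size matters for faithfulness: at 2 mm voxels every filter in the
4.5–9 mm range has sigma ≥ 0.95 voxels and is well represented discretely.
Coarser grids push sigma below half a voxel, where a sampled-and-normalized
kernel no longer carries its nominal width; the package's validation
defaults therefore keep 2 mm spacing and shrink the field of view rather
than the voxel density.

## The synthetic cohort generator

`make_phantom()` builds a deterministic piecewise-constant brain-like
object: an ellipsoidal "gray matter" shell (intensity `gm_wm_ratio`,
default 4 — the standard gray:white FDG contrast used by physical brain
phantoms) around a "white matter" core (intensity 1) whose boundary is
folded sinusoidally to mimic cortical convolutions, plus two zero-intensity
ventricles. All geometry is defined relative to the grid extent, so the
phantom scales exactly with the field of view.

`simulate_subject()` degrades the phantom through the four difference
sources, in order: a smooth multiplicative random field (white noise
smoothed to 20 mm FWHM, amplitude 5%) together with a global intensity
scalar (CV 5%) for inter-subject variability; a random rigid translation
(SD 0.5 mm per axis, cubic interpolation) for residual misregistration —
translation-only, because small misalignment acts on the average like a
mild blur, which is exactly the effect one parameter can reproduce; the
scanner's anisotropic Gaussian blur; and additive Gaussian noise with SD 5%
of mean gray-matter intensity, a standard post-reconstruction surrogate for
all stochastic signal variability (no projection-domain physics). Noise is
not clipped at zero: reconstructed PET images genuinely contain small
negative excursions, and clipping would bias cohort averages.

The variability magnitudes are not published quantities; they are
field-plausible surrogates chosen once and exposed as named spec fields so
sensitivity sweeps are one-line changes. Every subject draws its randomness
from a generator seeded by `(seed, subject_index)`, making each subject a
pure function of its arguments and cohorts extensible without reshuffling.

What the generator does *not* emulate: anatomical variability between
subjects (one shared phantom), spatially varying (radially dependent)
scanner PSFs, attenuation/scatter artifacts, or tracer kinetics. Passing
validation on these cohorts therefore demonstrates correctness of the
estimation machinery under the stated difference model, not performance on
any particular clinical archive.

## The validation harness

`run_validation()` mirrors the standard design: every scanner in turn is
the reference, every other scanner the test, at targets 6, 8 and 10 mm.
All cohorts descend from one shared phantom — the multicenter situation
where one population is imaged on different machines — with per-scanner
cohort sizes taken from the scanner profiles (12+16, 32+37, 35+38, 41+29
for HRRT, Biograph, Discovery and HR+). Each (pair, target) contributes an
XY and a Z record scored as `estimated − sqrt(target² − scanner_test²)`;
boundary-flagged records are kept and marked, never dropped. With four
scanners and three targets the matrix yields exactly 72 records.

Problem size: the validation matrix and the acceptance script run on a
48×58×48 voxel phantom at 2 mm spacing (96×116×96 mm field of view), the
package's desk-scale default balancing kernel fidelity (see above) against
a few minutes of single-core runtime for the 36 pair-target optimizations.

The behavior reproduced by the harness, asserted in the acceptance tests:

* at targets 8 and 10 mm, where every required filter exceeds 5 mm,
  estimates track the quadrature truth within a fraction of a millimetre
  (bounds 1.2 mm and 1.0 mm);
* at the 6 mm target the required filters shrink toward zero (for HR+ they
  *are* zero) and errors grow to the millimetre scale (bound 3 mm): a
  narrow filter changes the image too little to be separated from residual
  inter-cohort differences, and the median error at 6 mm exceeds that at
  10 mm;
* in the clean limit (no noise, no jitter, no subject variability) the full
  stack recovers planted filters to 0.3 mm, so the degradation above is a
  property of the data conditions, not of the optimizer.

## Known limitations

* A single global filter per scanner: no radially dependent PSF modelling.
* Scanner noise spectra are not modelled per scanner; systematic biases of
  very noisy high-resolution scanners (e.g. HRRT-like) are visible in the
  per-scanner mean signed errors but not corrected.
* The method assumes the reference is at least as coarse as the test set
  after target smoothing; components clamp to zero otherwise.
* Estimates for required filters below ~1 mm are unreliable by
  construction; prefer coarser targets when scanners are near-matched in
  resolution.
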