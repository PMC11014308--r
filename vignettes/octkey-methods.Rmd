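---
title: "Epidermal-thickness keys from OCT fingertip volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epidermal-thickness keys from OCT fingertip volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octkey)
```

## The pipeline in one paragraph

Optical coherence tomography (OCT) resolves the layered structure of
fingertip skin in depth: the skin surface, the epidermis, and the ridged
dermis–epidermis junction (DEJ) whose topography mirrors the surface
fingerprint — the *internal fingerprint*. `octkey` turns the per-column
distance between the surface and the DEJ (the epidermal thickness) into a
101×101 8-bit grayscale image that serves as a biometric key for spectral
image encryption: the plaintext is transformed with an orthonormal 2D
DCT-II, low-pass compressed, and multiplied elementwise by the resized key;
decryption divides by the key and inverts the transform. A synthetic OCT
phantom with exact ground truth makes every stage testable without
acquisition hardware.

## The phantom

`phantom_params()` / `generate_volume()` render a three-layer reflectivity
model per B-scan — air, epidermis, dermis — between two ground-truth
boundary fields:

* **Surface (upper boundary).** A mean depth (`surface_depth_px`, default
  60 px) plus a smooth random undulation (sd `surface_smooth_sd_px` = 3 px,
  correlation length `thickness_field_scale` = 30 px) plus the ridge field.
  Surface and internal fingerprints are anatomically co-registered, so the
  surface undulates in phase with the DEJ; the glass-flattening used by
  acquisition hardware is deliberately not modelled.
* **Ridge field.** A quasi-periodic oriented sinusoid: period
  `ridge_period_px` (36 px), peak-to-valley `ridge_amp_px` (24 px), with an
  orientation of 0.9 rad drifting slowly (±0.1 rad sd). The mean
  orientation leans the ridges across the slice axis so the ridge slope
  seen along one B-scan's columns stays below the boundary tracer's
  continuity budget; fingerprint ridges are in general oblique to the scan
  raster.
* **Thickness (lower boundary = upper + thickness).** Mean
  `mean_epi_thickness_px` (48 px), a weak smooth component
  (`thickness_smooth_sd_px` = 0.1 px), and pixel-scale DEJ roughness
  (`dej_jitter_px` = 0.8): each position is displaced by −a/0/+a with equal
  probability. The three-level form is deliberate — it bounds the
  column-to-column excursion of the DEJ at 2a px, which keeps the roughness
  *trackable* by a continuity-constrained tracer while staying uncorrelated
  between neighbouring positions. This roughness is what the key is made
  of.
* **Rendering.** Air 0.03, epidermis 0.5 with an exponential depth roll-off
  fixed at 0.67 optical depths across the mean band (so the band contrast
  is invariant to the pixel scale of the phantom), a mildly hyperreflective
  DEJ line (×1.2), dermis 0.11, multiplicative log-normal speckle
  (`speckle_sigma` = 0.12, unit mean), clipped to [0,1] and quantized to
  the 16-bit grid so TIFF round trips are lossless. The depth roll-off is
  what makes the en-face maximum intensity projection encode DEJ
  topography: the brightest voxel of a fixed en-face band sits at the top
  of the band, and its brightness decays with the band-top's depth below
  the surface, which varies with the ridge phase.
* **Pressure.** `apply_pressure()` scales the thickness field by
  `1 − compression_coeff·pressure` (0.005/kPa) and adds a smooth
  perturbation whose sd grows at 0.06 px/kPa, emulating non-uniform tissue
  redistribution between scans; each pressure is re-rendered with an
  independent speckle draw. The two coefficients were fixed once so that
  keys derived at 6/10/14 kPa have pairwise normalized cross-correlation
  in the ≈0.78–0.94 range, the regime reported for repeated scans of one
  finger under varying contact pressure; they are not revisited per
  experiment.

What the phantom does *not* emulate: real fingerprint minutiae statistics,
sweat ducts, glass-tilt artifacts, wave-optics speckle correlation, or the
true axial pixel pitch (no physical depth calibration is published for the
geometry we mirror, so all thicknesses stay in pixels). Tests passing on
the phantom therefore validate the *algorithmic* chain — tracing,
projection, counting, mapping, crypto, metrics — not clinical segmentation
accuracy on real tissue.

## Boundary segmentation

`segment_boundaries()` (method `"dp_gradient"`) traces each B-scan twice
with a minimum-cost path:

* **Cost.** Forward-difference axial gradient plus a boxcar step matched
  filter (4-row means above vs below). The forward difference has a single
  sharp extremum per layer transition, pinning the path to the exact row;
  the matched filter averages speckle so isolated noise pixels do not
  attract the path. The surface pass maximizes the dark→bright response
  (the traced row plus one is the first bright row); the DEJ pass
  maximizes bright→dark below the surface plus a minimum gap (3 px).
* **Two passes per boundary.** The median-filtered per-column cost minimum
  gives the slowly varying trend of the curve; the cost is then re-indexed
  relative to the trend (±8 rows) and traced with the ≤2 px per-column
  continuity constraint. The constraint therefore limits the jump of the
  *deviation from the trend*: the full jump budget remains available for
  pixel-scale DEJ roughness riding on a sloped ridge. On a single-column
  image the scheme degenerates to the per-column gradient extremum.
* **Validity.** A column is flagged when the gradient at its traced rows
  (±1 px) is weaker than `min_contrast` (0.025 intensity/px); a slice with
  more than half its columns flagged (e.g. a constant image) raises an
  error. The flag is advisory downstream: flagged columns keep their traced
  band in the binary masks, since the traced path is still the best
  available estimate there.

The tracer is registered behind `register_segmentation_method()`, so a
learned segmenter can replace it without touching the rest of the pipeline.

## Envelope ROI, projection, and the key

`locate_dej_extrema()` finds ridge tops and papillae valleys on the traced
DEJ after a moving-average smoothing (window ≈ period/4; the period is a
configuration input, as is the minimum extrema separation ≈ period/3).
`build_envelope_roi()` passes natural cubic splines through the raw extreme
values at the detected positions — positions from the smoothed curve,
values from the raw curve, so the envelope amplitude is not attenuated —
then applies a lateral moving average to damp spline oscillation between
knots (a no-op for a clean periodic ridge, whose envelopes are constant),
extends by edge values, and pads the enclosed mask by 3 px so the true
junction stays inside despite pixel-scale roughness. Fewer than two extrema
of a kind (a flat DEJ) falls back to a constant band with a warning.

`mip_project()` takes the depth maximum within each slice's mask —
the en-face internal fingerprint (width × slices). `select_center_roi()`
marks the 101×101 key region either at explicit coordinates (mirroring
manual labelling) or automatically at the centroid of smoothed band-pass
ridge energy. `crop_epidermis_stack()` and `count_thickness()` reduce the
binary epidermis masks to the 101×101 integer thickness matrix;
`linear_to_gray()` maps it affinely onto [0,255] using the per-key
minimum/maximum (no absolute thickness calibration exists, and the
recorded bounds make the map invertible); the quadratic stretch
`DB = round(DA²/255)` darkens the low end. Rounding is half-away-from-zero
throughout, pinned so keys are bit-reproducible across platforms.

## Encryption

The 2D DCT-II uses orthonormal scaling (`dct2()` / `idct2()` are exact
transposes), the low-pass filter keeps the top-left
`ceil(frac·N)×ceil(frac·M)` coefficient block (default frac 0.5; a block
mask keeps the invertibility bookkeeping exact), the filter is applied
before key multiplication, and "fusion" is elementwise multiplication.
Keys are resized bicubically (Keys kernel, a = −0.5, pixel-center
alignment — the identity at the source grid) and offset/clamped to
[1,256] so decryption's elementwise division is always defined; the offset
is recorded in the scheme parameters. With the full spectrum and the
correct key the round trip is bit-exact, because the plaintext is integer
and the reconstruction error is at machine precision before rounding.

## Evaluation metrics

SSIM is the *global* single-window form computed from whole-image moments
with the conventional stabilizing constants `(0.01·255)²` and `(0.03·255)²`
on the mean and variance terms respectively. A published variant of the
formula conflates the two constants in the denominator; we treat that as a
typographical slip and implement the standard form, but expose
`variant = "printed"` so the alternative can be compared explicitly.
NCC is `Σab/√(Σa²Σb²)`. Adjacent-pixel correlation samples J = 5000 pixel
pairs with replacement (seeded; the sampling scheme is otherwise
unspecified in the literature we follow) in the horizontal, vertical or
diagonal direction and computes the Pearson correlation; a constant image
is a flagged degenerate case. Entropy is Shannon entropy of the 256-bin
gray histogram, bounded by 8 bits.

## Robustness experiments

`pressure_study()` shares one unloaded truth across pressures, re-renders
each scan with fresh speckle, reuses the first scan's key region (a fixed
landmark), and fills the symmetric unit-diagonal NCC matrix.
`noise_attack()` adds zero-mean Gaussian noise of variance 0.1 on the unit
intensity scale — on the 0–255 scale that variance would be imperceptible,
so the normalized scale is the only sensible reading — then clips and
requantizes. `data_loss()` zeroes a centered square of side
`round(√fraction·min(N,M))` (ties toward the top-left), the natural
square reading of a central loss of a stated area fraction.
`key_randomness_report()` averages the three directional correlations over
10 sampling seeds and attaches entropies and histograms.

## Problem sizes and numerical choices

The full-size phantom (400 slices × 248 × 345) runs the whole key pipeline
in about two minutes on one core. The test-suite and acceptance-script
phantoms use a scaled geometry (130 slices × 90 × 160, period 24,
amplitude 14, thickness 28) with identical band contrast, roughness and
ridge-slope *proportions*; the properties checked are scale-free, and the
vignette-level choice keeps the default validation runs fast enough to be
re-run routinely. Envelope interpolation order (cubic), the smoothing
window (period/4), the extrema separation (period/3) and the ROI pad
(3 px) are configuration, not constants of the method.

## A structural limitation, stated plainly

Two groups of desirable properties of this design pull against each other
through one quantity: the number of distinct integer thickness counts in a
key.

* Faithful ground-truth recovery by a tracer with a ≤2 px per-column
  continuity constraint requires the DEJ roughness to have small, bounded
  column-to-column increments. For a thickness sequence with near-zero
  lag-1 correlation, the rms increment is ≈ sd·√2, so trackable keys have
  a value spread of only a few pixels — here about six distinct counts.
* Statistical indistinguishability of a key from a random 8-bit image —
  gray-level entropy near 8 bits, and wrong-key decryption that destroys
  the plaintext — requires on the order of a hundred well-occupied levels.

No parameter setting satisfies both; published keys with entropy ≈7.8 bits
*and* high cross-scan repeatability imply segmentation noise far larger
than a 2 px tolerance admits. This package resolves the tension in favour
of verifiable recovery: keys are repeatable (cross-pressure NCC ≈0.8–0.94),
spatially uncorrelated (|COR| < 0.1), and discriminative between regions
(key-vs-key SSIM ≈ 0.01), but their gray-level entropy is far below 8 bits,
and decryption with a wrong few-level key degrades the image only partially
(global SSIM typically 0.2–0.9) rather than destroying it — the resized-key
ratio concentrates near 1. The corresponding checks are kept in the test
suite and fail honestly; treating the epidermal-thickness map as a
high-entropy cryptographic key requires either a segmenter free of
continuity constraints or an explicit key-conditioning step, both outside
this package's scope.
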