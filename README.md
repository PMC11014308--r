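# octkey

Biometric image encryption keyed by the epidermal thickness of fingertip
skin, as imaged by optical coherence tomography (OCT).

## The problem

Surface fingerprints wear, smudge, and can be lifted. The *internal
fingerprint* — the ridged dermis–epidermis junction (DEJ) a few hundred
micrometres below the surface — carries the same pattern but is protected
from wear and hard to forge without volumetric imaging. A 3D OCT scan of a
fingertip resolves both the skin surface and the DEJ in every
cross-sectional B-scan, so the per-column distance between them — the
**epidermal thickness map** — is a personal, internally-sourced quantity
that can serve as an encryption key.

`octkey` implements the full chain, for researchers in optical biometrics
and image encryption:

1. **Phantom** — a synthetic 3D OCT fingertip volume (ridged DEJ,
   co-registered surface, speckle, pressure-dependent compression) with
   exact ground truth, so the whole pipeline is testable without hardware.
2. **Segmentation** — two-pass dynamic-programming tracing of the surface
   and DEJ in each B-scan (a pluggable stand-in for a learned segmenter).
3. **Fingerprint** — the en-face internal fingerprint by maximum intensity
   projection (MIP) over the DEJ ridge-envelope region, and selection of a
   centered 101×101 key region.
4. **Keygen** — column-wise white-pixel counts of the binary epidermis
   stack → 101×101 thickness matrix → linear map to [0,255] → quadratic
   stretch `DB = DA²/255` → the 8-bit key image.
5. **Crypto** — encryption `C = lowpass(DCT(P)) ⊙ K` and decryption
   `P̂ = clip(round(IDCT(C ⊘ K)))`, with the key resized bicubically to the
   plaintext shape and offset to [1,256] so the division is always defined.
6. **Metrics & robustness** — global SSIM, normalized cross-correlation
   (NCC), adjacent-pixel correlation, gray-level entropy and histograms;
   experiment drivers for pressure insensitivity, wrong-key security,
   noise attacks, central data loss, and key-randomness comparison.

## Worked example

```r
library(octkey)

params <- phantom_params(n_slices = 130, depth_px = 90, width_px = 160,
                         ridge_period_px = 24, ridge_amp_px = 14,
                         mean_epi_thickness_px = 28, surface_depth_px = 20,
                         thickness_field_scale = 16, seed = 2)
ph <- generate_volume(params)          # volume + ground truth
ph$volume
#> OCT volume: 130 slices x 90 depth x 160 width px (spacing 25 um)
#>   intensity range [0.0172, 0.8039]

key <- generate_key(ph$volume, ridge_period_px = 24)
key
#> Thickness-map key image: 101 x 101 px, gray range [0, 255]
#>   linear map from counts [27, 31]; non-linear stretch: TRUE

plain  <- demo_image(256)              # synthetic 256x256 test scene
rk     <- resize_key(key)              # bicubic 101x101 -> 256x256, values in [1,256]
cipher <- encrypt_image(plain, rk, lowpass_frac = 0.5)
cipher
#> DCT-domain cipher: 256 x 256, values [-530650.09, 249691.42], low-pass fraction 0.5

decrypted <- decrypt_image(cipher, rk)
metrics_report(plain, decrypted, seed = 1)
#> SSIM 0.9936 | NCC 0.9994 | COR h/v/d 0.9763/0.9723/0.9704 | entropy 6.5674 bits
```

The decrypted image reproduces the plaintext almost perfectly (SSIM 0.99;
with `lowpass_frac = 1` the round trip is bit-exact). The same key derived
from re-scans under different contact pressures stays usable:

```r
pressure_study(params, c(6, 10, 14))
#> Cross-pressure key NCC matrix (kPa):
#>         6     10     14
#> 6  1.0000 0.8474 0.9021
#> 10 0.8474 1.0000 0.7766
#> 14 0.9021 0.7766 1.0000
```

Off-diagonal NCC near 0.8–0.9 means the thickness pattern survives the
pressure change; the unit diagonal is the self-correlation of a key.
`noise_attack()`, `data_loss()` and `key_randomness_report()` drive the
remaining robustness experiments, and `run_pipeline()` orchestrates
phantom → key → cipher → metrics end to end with a persisted manifest.
A thin command-line front end lives at `inst/cli/octkey.R`.

## Known limitation

A thickness key traced under a ≤2 px per-column continuity constraint has
only a handful of distinct gray levels, so it cannot simultaneously look
like a uniform random 8-bit image. Keys from this pipeline are repeatable,
spatially uncorrelated and region-discriminative, but their gray-level
entropy is low and a wrong key degrades rather than destroys the
plaintext. The methods vignette (`vignettes/octkey-methods.Rmd`) derives
why these goals conflict and which side this package takes; the test suite
keeps the conflicting checks and lets them fail honestly.
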