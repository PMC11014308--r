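Package: octkey
Title: Epidermal-Thickness Biometric Keys from OCT Fingertip Volumes for
    Spectral-Domain Image Encryption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive biometric encryption keys from the epidermal
    thickness of fingertip skin imaged by optical coherence tomography (OCT).
    Includes a synthetic OCT phantom generator with known ground-truth skin
    boundaries and a pressure-deformation model, dynamic-programming
    segmentation of the epidermal surface and the dermis-epidermis junction,
    en-face internal-fingerprint reconstruction by maximum intensity
    projection, generation of a 101 x 101 grayscale thickness key, encryption
    and decryption of grayscale images in the discrete cosine transform
    domain using the key, image-quality and randomness metrics (structural
    similarity, normalized cross-correlation, adjacent-pixel correlation,
    gray-level entropy), and a robustness suite covering pressure variation,
    wrong-key decryption, noise attacks and data loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
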