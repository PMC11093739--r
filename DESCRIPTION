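Package: duofuse
Title: Dual-View Light-Sheet Stack Fusion and Single-Cell Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing toolkit for open-top dual-view light-sheet
    microscopy. Registers image stacks acquired by two opposing detection
    objectives, scores per-plane image quality by the Shannon entropy of
    the normalized discrete cosine transform, selects the depth at which
    to switch views, and blends the stacks with a sigmoidal weight ramp.
    Also provides optical-characterization math (Gaussian line-profile
    fits, FWHM, beam waist, Rayleigh length, effective numerical
    aperture, bead-based PSF measurement), single-cell track statistics
    (origin-anchored 3D mean square displacement, step speeds, path
    lengths), 3D shape features from stitched 2D label masks, and seeded
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
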