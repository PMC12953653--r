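Package: psf4d
Title: Physics-Guided Restoration for Liquid-Lens Continuous-Zoom Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spatially-variant, multi-wavelength,
    magnification-dependent (4D) point spread function of a liquid-lens
    continuous-zoom microscope from a Zernike pupil model, degrades phantom
    specimens through it to build paired training data, and restores degraded
    images with a content-adaptive learnable Wiener front end followed by a
    degradation-guided attention network trained under a physics-constrained
    loss. Includes the two-group zoom optics equations, an HDF5-backed PSF
    dictionary with MTF computation, a reverse-mode autodiff tape for the
    learnable components, and a PSNR/SSIM evaluation harness across
    magnifications.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    png,
    tiff,
    rhdf5,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
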