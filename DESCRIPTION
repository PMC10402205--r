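Package: ulmpact
Title: Spherical-Array Photoacoustic Tomography and 3D Ultrasound
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for volumetric photoacoustic
    computed tomography (PACT) and ultrasound localization microscopy (ULM)
    with a spherical-cap receiver array. Provides an analytic acoustic
    forward simulator (point photoacoustic sources, pulse-echo scatterers,
    flowing microbubbles, static clutter), 3D delay-and-sum beamforming for
    one-way photoacoustic and two-way synthetic-aperture ultrasound data
    (direct and sparse-operator forms), Wiener impulse-response
    deconvolution, two-wavelength linear unmixing of haemoglobin oxygen
    saturation, the full ULM chain (motion rejection, SVD clutter
    filtering, slow-time band-pass and directional filtering, power
    Doppler, sub-voxel radial-symmetry localization, Hungarian-assignment
    tracking, super-resolved density and velocity rendering), morphological
    vessel segmentation with per-vessel structural and functional
    statistics, and a reproducible configuration-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
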