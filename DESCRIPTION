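Package: holocyte
Title: Single-Cell Biophysics from Combined Quantitative Phase Imaging and
    Brillouin Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing chain for label-free biophysical cytometry of
    spherical cells. Converts a single off-axis hologram into an unwrapped,
    background-corrected phase map, fits the spherical cell geometry with a
    calibrated circular Hough transform, and derives refractive index, dry
    mass, density and water content from a two-component mixture model.
    Fits Stokes/anti-Stokes Lorentzian pairs to VIPA Brillouin spectra on an
    FSR-calibrated frequency axis and combines both modalities into the
    longitudinal storage and loss moduli, longitudinal viscosity and loss
    tangent. Includes seeded forward simulators for interferograms and
    Brillouin spectra so the full pipeline is testable without instrument
    data, plus cohort-level summaries, Welch tests and correlation fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
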