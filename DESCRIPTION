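Package: lambdamap
Title: Poisson Spectral Unmixing and Fraction Mapping for Hyperspectral
    Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing lambda-stack (multi-channel spectral)
    fluorescence images of solvatochromic membrane probes such as laurdan.
    Provides per-pixel nonnegative spectral decomposition under a Poisson
    noise model (fixed-reference and blind NMF modes with multiplicative
    Kullback-Leibler updates), fractional-intensity mapping of two-component
    decompositions with intensity-scaled discrete-colour rendering,
    generalized polarisation (GP) conversion, 2D intensity histograms with
    polygon gating, band-ratio emulation of flow-cytometry readouts, and a
    ground-truthed synthetic scene generator (vesicle and cell phantoms with
    Poisson shot noise) so that the whole pipeline can be exercised and
    validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
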