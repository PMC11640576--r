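Package: octsim
Title: Fast Phase-Sensitive Fourier-Domain OCT Image Formation with Point Scatterers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Fourier-domain optical coherence tomography (OCT) signals
    for samples of discrete point scatterers under the first-order Born
    approximation. The incident beam is the vectorial focal field of an
    aplanatic objective, evaluated rigorously through the Bessel-reduced
    Debye-Wolf integral, and accelerated by two devices: a Taylor expansion of
    the phase-factored field about a sparse source-point grid, and a
    multi-spectral regression (MSR) scheme that reconstructs the sample-arm
    spectrum at every wavenumber from fields stored at a few anchor
    wavenumbers. Supports phase-sensitive A-/B-/C-scan simulation, rapid
    re-simulation under axial scatterer displacement (optical coherence
    elastography workflows), synthetic speckle phantoms with uniform-strain and
    elliptic-inclusion displacement fields, and a validation harness comparing
    fast backends against the rigorous quadrature oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
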