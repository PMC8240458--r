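Package: fibrefocus
Title: Simulation of Binary-Amplitude Wavefront Shaping Through Multimode Fibres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates focusing of coherent light through a multimode fibre
    (modelled as a random complex transmission matrix) with binary amplitude
    modulation by a digital micromirror device. Implements four non-holographic
    focusing algorithms: the real-valued intensity transmission matrix (RVITM)
    method with Hadamard-basis characterisation and top-P thresholding,
    intensity-only phase retrieval of transmission-matrix rows from random
    binary probes, a conditional-probability mask construction, and a genetic
    algorithm driven by the peak-to-background ratio (PBR). Also provides the
    closed-form theoretical PBR for binary amplitude modulation, including the
    optimal phase-difference bound, and a benchmark harness that compares all
    methods on matched media with machine-readable reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
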