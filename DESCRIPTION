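Package: ptychor
Title: Ptychographic Phase Retrieval with Projection and Maximum-Likelihood Engines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative ptychographic reconstruction of a complex object
    transmission function and illumination probe from far-field diffraction
    intensities. Implements the alternating-projections, difference-map,
    relaxed averaged alternating reflections (RAAR) and regularized PIE
    (rPIE/mPIE) engines, a gamma-parameterized maximum-likelihood refinement
    stage, mixed-state probe modes with orthogonalization, annealing-based
    scan-position correction, and a batched accumulate/reduce/broadcast update
    scheduler that makes reconstructions invariant to batch size and worker
    count. A forward simulator generates ground-truthed synthetic datasets
    (procedural phantom, jittered raster scans, optional Poisson counting
    noise), and postprocessing removes the global phase, linear phase-ramp and
    scale ambiguities for quantitative comparison against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
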