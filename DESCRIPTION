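Package: scopeqc
Title: Automated Confocal Microscope Performance Monitoring
Version: 0.1.0
Authors@R: person("Core Facility", "Imaging", email = "imaging@example.org",
    role = c("aut", "cre"))
Description: Batch quantification of confocal microscope performance from
    keyword-named TIFF recordings: laser intensity stability and noise,
    axial resolution and chromatic correction from mirror reflection scans,
    field illumination uniformity, multi-channel bead co-registration,
    point spread function metrology, spectral detector (lambda scan)
    accuracy, motorised stage repeatability and accuracy, and Z-focus
    drift. Measurements are appended to tab-delimited text files and to an
    amendable per-system, per-objective HTML record. A seeded synthetic
    data generator produces every input kind with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
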