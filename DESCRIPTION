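Package: photokin
Title: Photocycle Kinetics and Global-Fit Analysis of Time-Resolved
    Difference Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-resolved difference-absorbance
    spectroscopy of microbial rhodopsin photocycles. Provides a data model
    and lossless text I/O for wavenumber-by-time difference matrices
    (merged step-scan and rapid-scan FTIR, flash-photolysis UV/VIS),
    first-order reaction-network machinery (rate matrices, populations,
    apparent rates, half-life conversions, a catalogue of candidate
    L-state topologies), a forward generator of synthetic datasets from
    band-composed species spectra, a weighted multi-exponential global
    fit by variable projection with per-channel amplitude spectra and
    offsets, and photocycle-level interpretation: species-associated
    difference spectra, marker-band kinetics and transition assignment,
    band detection, spectrum scaling, and kinetic-topology discrimination
    by BIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
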