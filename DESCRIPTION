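Package: macromech
Title: Cortical Mechanics, Membrane Tethers and Motility of Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of macrophage cortical mechanics and
    motility. Implements the magnetic-pincher pipeline (subpixel bead
    detection, optimal-assignment tracking, cortex thickness and
    dipole-pair pinching force, thin-layer stress-strain conversion and
    tangential-modulus fitting in a stress window), membrane-to-cortex
    attachment estimation from atomic-force-microscopy tether pulling
    (break-force detection, Brochard-Wyart force-velocity model,
    Monte-Carlo fitting of the attachment parameter Alpha and its Z-test
    comparison), migration track statistics (median speed, confinement
    ratio, forward migration index, transwell, rolling/sticking and
    tissue-infiltration summaries) and morphodynamics (podosome
    appearance/maintenance/disappearance classification, ruffle and bleb
    retraction metrics). A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
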