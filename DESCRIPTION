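Package: nucleozone
Title: Subnuclear Zoning, Locus Mobility, DIM Detection and Fluctuation
    Analysis for Yeast Nuclear-Periphery Relocation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of nuclear-periphery relocation assays in
    budding yeast: classification of fluorescently tagged chromosomal loci
    into three equal-area nuclear zones from Nup49-marked nuclear envelope
    images, detection of diffraction-limited foci, the spindle pole body and
    damage-induced microtubules (DIMs) in multi-channel stacks, drift-corrected
    mean-squared-displacement curves with radius-of-constraint estimation, and
    Luria-Delbruck fluctuation analysis of chromosome-end-loss rates by
    Ma-Sandri-Sarkar maximum likelihood with profile-likelihood confidence
    intervals and likelihood-ratio tests.  A ground-truthed synthetic-scene
    generator renders spherical nuclei, point-source foci and linear
    microtubule structures with Gaussian optics and Poisson noise, so every
    stage of the pipeline is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
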