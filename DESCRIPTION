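Package: brainrheo
Title: Viscoelastic Model Identification and Elastography Analysis for Brain Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the rheology of soft neural tissue from
    magnetic resonance elastography (MRE) and flat-punch nanoindentation.
    Implements the complex dynamic shear moduli of four rheological models
    (Maxwell, Voigt, springpot, standard linear solid), multi-start
    Nelder-Mead identification of frequency-independent viscoelastic
    parameters from storage/loss frequency sweeps, a synthetic elastography
    chain (shear-wave phantom simulation, eight-phase demodulation, algebraic
    Helmholtz inversion, regional boxplot statistics), flat-punch
    nanoindentation modulus conversions, myelin-fraction scoring of stained
    histology sections, and a post-mortem stiffening report built from
    regional storage and loss moduli.
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
    jsonlite,
    RNifti
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
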