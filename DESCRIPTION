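Package: nmseg
Title: Cascaded Segmentation and Hyperintense-Area Quantification of the
    Substantia Nigra in Neuromelanin-Sensitive MRI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated assessment of the substantia nigra pars
    compacta (SNpc) in neuromelanin-sensitive MRI: a two-stage (cascaded)
    U-net that first segments the midbrain and then the SNpc within it, a
    background-referenced intensity threshold statistic (the hyperintense
    SNpc area above the midbrain-background mean plus k standard
    deviations), and the accompanying evaluation layer (Dice similarity
    with rating bands, ROC/AUC with the DeLong comparison of correlated
    curves, rank correlations and group tests). A synthetic midbrain
    phantom generator with ground-truth masks and a controllable
    Parkinson's-disease effect makes the full pipeline testable without
    patient data. The convolutional networks and their optimisation are
    implemented natively in R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
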