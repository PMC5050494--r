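Package: smlmtools
Title: Quantitative Analysis of Single-Molecule Localization Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for extracting quantitative information from single-molecule
    localization microscopy (SMLM) data such as dSTORM or PALM. Reads
    localization tables produced by common localization software (rapidSTORM,
    ThunderSTORM), registers colour channels from fiducial markers, estimates
    localization precision from photon statistics and from nearest-neighbour
    distance distributions (NeNA), computes Ripley K/L/H second-order
    statistics, DBSCAN and OPTICS density clustering with polygon-based
    cluster morphology, coordinate-based colocalization (CBC) and interaction
    domains, Fourier ring correlation (FRC) resolution estimates, and
    molecular stoichiometry from photoswitching (blinking) kinetics via a
    negative-binomial counting model. A ground-truth simulator for SMLM
    localization data is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    xml2,
    mgcv,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
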