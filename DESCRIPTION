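Package: spanflex
Title: Weighted Multistate Ensemble Geometry, SAXS and Synapse-Image
    Analysis for Bispecific T Cell Engagers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of weighted conformational ensembles of multi-domain
    molecules such as bispecific T cell engagers (TcEs). Reads multistate
    PDB ensembles with state weights, superposes states on a reference
    subcomplex, and computes weight-adjusted paratope and membrane-anchor
    spacing distributions, domain tilt angles, radius of gyration,
    center-of-mass and rotational flexibility, and effective disorder.
    Includes a coarse-grained Debye engine for small-angle X-ray scattering
    (SAXS) profiles with Guinier fitting, dimensionless Kratky transforms,
    chi goodness-of-fit, and exhaustive small-pool multistate ensemble
    selection, plus Pearson colocalization and normalized per-synapse
    signal quantification for two-channel membrane-interface images. A
    synthetic-data module generates articulated multi-domain ensembles,
    SAXS mixtures and synapse images with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    EBImage,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
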