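Package: rhlBminer
Title: Reference-Anchored Mining of Polymorphic Enzyme Gene Variants
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multilayer DNA-protein mining toolkit for discovering
    functionally relevant polymorphic variants of a reference enzyme CDS,
    with the rhamnosyltransferase gene rhlB as the worked case. Provides
    reference-anchored mutation profiling (transition/transversion,
    silent/missense/nonsense, per-line densities), repository cleansing
    filters, mutational hotspot and gap-constrained mismatch-motif mining,
    Needleman-Wunsch global alignment with user-supplied substitution
    matrices, protein-level substitution annotation (structural elements,
    hydropathy/charge/polarity deltas, Das-Pappu charge patterning
    FCR/NCPR/kappa, binding-site proximity scoring), calibration-curve
    quantification (limit of detection, MAPE, censored inversion, fold
    change, droplet contact-angle geometry), a seeded synthetic repository
    generator with ground-truth mutation tables, and a cycle-based mining
    orchestrator with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    Biostrings
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SequenceMatching, Alignment, Genetics, SNP, Software
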