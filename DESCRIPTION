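Package: pcpfit
Title: Protein Correlation Profiling of Membrane-Associated Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deconvolves per-fraction protein abundance profiles from
    size-exclusion chromatography (SEC) co-fractionation experiments into
    Gaussian elution peaks with BIC model selection, converts reproducible
    peak positions into apparent native masses via a standards regression,
    and classifies the oligomerization state of each protein from the ratio
    of apparent to monomer mass (R_app).  Additional stages filter true
    membrane-associated proteins using sucrose velocity gradient profiles,
    flag dual-localized proteins with mass shifts between cytosolic and
    membrane pools, apply a replicate presence-absence acceptance rule for
    co-immunoprecipitation interactors, classify ortholog coverage of
    reference metazoan complexes, and provide replicate-correlation and
    profile-clustering analytics.  A seeded simulator generates ground-truth
    labeled datasets emulating MaxQuant-style quantification tables so every
    stage can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
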