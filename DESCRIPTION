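Package: ecophys
Title: Catabolic Energetics, Growth Kinetics, and Recruitment Statistics
    for Marine Bacterioplankton Ecophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for the ecophysiology of facultatively
    chemolithotrophic marine bacterioplankton. Computes standard and in-situ
    Gibbs energies of catabolic reactions (heterotrophic oxidation of composite
    dissolved organic carbon via the nominal oxidation state of carbon, and
    thiosulfate oxidation to sulfate) with extended Debye-Huckel (B-dot)
    activity coefficients at 25 C; estimates specific growth and death rates in
    doublings per hour from sparse cell-density time series by segmented
    log-linear regression; performs chlorinity-based salinity arithmetic for
    media design; normalizes genome-by-sample read-recruitment tables to RPKM
    and TPM and analyzes community structure with weighted UniFrac distances,
    principal coordinate analysis, ANOSIM permutation tests, and per-genome
    abundance-environment regressions; summarizes genome cohorts; and ships a
    seeded synthetic-data generator so every stage has a ground-truth-known
    test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
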