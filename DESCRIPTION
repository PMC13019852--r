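Package: fishcoloc
Title: Quantification and Statistics for Duplex Fluorescence In Situ
    Hybridization Colocalization Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Area-based quantification of duplex fluorescence in situ
    hybridization (fISH) images of the basal forebrain: frozen-macro channel
    thresholding, condensed cholinergic (ChAT+) region construction with
    crack filling, partition of OXTR signal inside and outside cholinergic
    regions, per-specimen mRNA metrics and percent colocalization, and the
    downstream statistics of a postmortem autism cohort study: neurotype
    group comparison with residual diagnostics and estimated marginal means,
    mRNA-receptor-binding correlations, linkage-disequilibrium (D') estimation
    by two-locus EM, ridge regression association with permutation p-values
    and FDR correction, and age correlations with oldest-specimen sensitivity.
    Includes a synthetic-data generator (images, cohort, genotypes) carrying
    the statistical structure the analysis assumes, so the full pipeline is
    testable without donor tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    emmeans,
    jsonlite,
    lmtest,
    stats,
    tiff,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
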