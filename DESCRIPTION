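Package: fampgs
Title: Family-Based Polygenic Score Analysis with Twin Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how a polygenic score (PGS) relates to a
    phenotype in twin-family data, and for telling direct genetic effects
    apart from indirect (genetic-nurture) and confounding pathways. Provides
    a twin-family simulator with direct effects, passive gene-environment
    correlation, shared family environment, phenotypic assortative mating and
    population stratification; genotype-matrix utilities (MAF filtering, LD
    pruning, ancestry principal components); summary-statistic BLUP (SBLUP)
    effect-size reweighting and PGS computation with allele matching;
    covariate-adjusted association with cluster-robust standard errors and
    incremental R-squared; the within/between-family decomposition fitted by
    a random-intercept REML model; and gene-environment-correlation
    diagnostics based on Fisher-transformed correlation confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    sandwich,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
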