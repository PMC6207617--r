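Package: sociovar
Title: Multilevel Variance Partition of Repeatedly Measured Sociability Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Partitions the population variance of a repeatedly measured,
    multi-instrument behavioural phenotype ("sociability") into trait
    (between-individual), indicator (instrument), state (within-individual)
    and residual components using a crossed random-intercepts linear mixed
    model estimated by restricted maximum likelihood, with
    genotype-moderated variance components as an indirect test of
    gene-environment interaction. Includes psychometric scale scoring with
    reference-wave standardisation, oxytocin-pathway SNP risk coding and a
    cumulative genetic risk score, profile-likelihood confidence intervals
    for variance components, per-indicator genotype association tests, and
    a synthetic accelerated-longitudinal cohort generator so the whole
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    lme4,
    vcfR,
    optparse,
    MASS,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
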