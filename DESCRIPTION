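Package: neuromediate
Title: Genotype-Brain-Behavior Mediation Analysis for Imaging Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An imaging-genetics analysis chain linking candidate-gene
    genotypes, regional cortical morphometry and behavioral outcomes.
    Provides genotype quality control (allele frequencies, exact and
    chi-square Hardy-Weinberg tests, pairwise linkage-disequilibrium r^2
    via a two-locus EM algorithm, minor-allele-carrier coding),
    mass-univariate general linear model screening of SNP, region-of-interest
    morphometry and behavior associations with Bonferroni correction,
    covariate-adjusted single-mediator analysis with case-resampling
    bootstrap and bias-corrected accelerated (BCa) confidence intervals
    and p-values, a Freedman-Lane permutation alternative, and a seeded
    synthetic-cohort generator so the whole pipeline can be exercised and
    validated without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
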