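Package: mirtld
Title: miRNA Targetome Variants, Linkage Disequilibrium and Case-Control
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes GWAS variants falling in miRNA binding-site regions
    of inflammatory-pathway genes via linkage-disequilibrium proxy expansion
    and interval intersection, and analyzes the selected variants in
    case-control cohorts: Hardy-Weinberg testing, five genetic-model
    contrasts with crude and covariate-adjusted odds ratios, EM two-locus
    haplotype-frequency estimation, D-prime and r-squared linkage statistics,
    and cumulative genotype/haplotype comparisons across phenotype and BMI
    strata. Includes a synthetic-data generator with known ground truth so
    the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
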