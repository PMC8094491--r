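Package: neotwas
Title: Multi-Tissue Transcriptome-Wide Association Analysis with
    Repeated-Measure-Aware Weight Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for transcriptome-wide association studies (TWAS)
    across multiple neocortical tissues.  Trains cis-variant predictive
    weights for gene expression (top1, BLUP, lasso, elastic net) with
    cross-validation folds that keep all samples from an individual
    together, gates genes on REML cis-heritability, associates imputed
    expression with a trait through GWAS summary statistics, refines loci
    with joint/conditional testing, summary-data Mendelian randomization
    and Bayesian colocalization, and expands hits into co-expression gene
    sets with cell-type enrichment tests.  Includes a synthetic-cohort
    generator with LD-structured genotypes and known ground truth so the
    whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
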