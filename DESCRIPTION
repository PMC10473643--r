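Package: metawas
Title: Imputation-Based Proteome- and Transcriptome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains cis-window elastic-net prediction models of protein and
    gene-expression levels from genotype dosages, combines the model weights
    with external GWAS summary statistics and a linkage-disequilibrium
    reference panel to obtain gene-level association z-scores for quantitative
    traits (PWAS/TWAS), and compares association profiles across omic layers
    via signed log p-value concordance, tissue-wise sign tests, and per-gene
    weight decompositions. Includes a synthetic cohort generator with
    LD-structured genotypes, sparse cis-genetic omic architecture,
    hidden-factor structure, and marginal GWAS summary statistics, so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
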