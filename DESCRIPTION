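Package: gxescan
Title: Transcriptome-Informed Gene-Based Gene-Environment Interaction Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based gene-environment (GxE) interaction analysis for
    case-control studies, informed by genetically predicted gene expression.
    Trains per-gene cis-expression weight models (top eQTL, LASSO,
    elastic net) on a reference expression panel with REML SNP-heritability
    gating, then tests each gene for interaction with an environmental
    exposure using a mixed-effects score test: a 1-df fixed-effect test on
    the predicted-expression-by-exposure term, a variance-component test for
    residual SNP-by-exposure effects with a mixture-of-chi-squares null, and
    adaptive and Fisher combinations of the two component p-values.
    Includes a genome-wide scan driver with per-exposure eligibility rules,
    Bonferroni and Benjamini-Hochberg multiple-testing correction, genomic
    inflation diagnostics, and a synthetic-data generator for LD-structured
    genotypes, heritable expression and ascertained case-control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
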