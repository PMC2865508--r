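Package: esnpnet
Title: Expression-Associated SNP Set Enrichment and Causal Co-Expression
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether SNPs associated with gene expression
    (eSNPs) in metabolic tissues are enriched for association with type 2
    diabetes in genome-wide association studies, using matched random
    resampling stratified by minor allele frequency, gene proximity and
    linkage-disequilibrium structure.  Includes Kruskal-Wallis cis/trans
    eQTL mapping with permutation-based empirical FDR, LD expansion of SNP
    sets at a correlation threshold, weighted co-expression network
    construction with topological overlap and module eigengenes,
    likelihood-based causal/reactive/independent model selection at QTL in
    an F2 intercross, hypergeometric gene-set enrichment, knockout
    expression signatures with Storey q-values, and a synthetic-data
    module that emulates the genotype, expression, GWAS and cross data
    needed to exercise every stage at desk scale.
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
    igraph,
    fgsea,
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
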