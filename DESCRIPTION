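Package: mqtlnet
Title: Multi-Environment mQTL Mapping and Causal Metabolite Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-metabolite association studies in replicated
    multi-environment plant trials. Provides a synthetic-data generator with a
    known causal metabolome, SNP quality control and Box-Cox variance
    stabilization, adjusted entry means and cross-environment BLUEs, one-step
    REML variance components with entry-mean heritability and per-environment
    repeatability, metabolite correlation structure with average-linkage
    clustering and Mantel comparison of metabolomic and genomic distances,
    kinship-corrected mixed-model mQTL scans with SNP-by-environment testing,
    FDR control and genotypic-variance decomposition, and causal
    phenotype-network inference combining a PC-skeleton with QTL-supervised
    edge orientation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    vegan,
    igraph,
    ape,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
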