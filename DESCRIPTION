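Package: eqtlenrich
Title: Tumor cis-eQTL Scanning with Molecular-Covariate Adjustment and
    GWAS Signal Enrichment for Regulator Target Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a cis-expression quantitative trait locus (eQTL)
    analysis for tumor cohorts in which gene expression is first adjusted
    for somatic copy number and CpG methylation by per-gene linear models,
    the expression variance explained by each molecular layer is
    decomposed, and adjusted expression is scanned for cis associations
    around risk loci with linkage-disequilibrium proxy expansion, Wald
    tests and Benjamini-Hochberg false discovery rate control.  A second
    component tests differential-expression-defined target-gene sets for
    enrichment of genome-wide association signal via window-based
    SNP-to-gene assignment, two-sample Kolmogorov-Smirnov tests,
    threshold Fisher's exact tests and preranked permutation gene set
    enrichment analysis.  A synthetic-data module generates genotype,
    expression, copy-number, methylation, GWAS summary and
    differential-expression inputs with known planted structure so the
    whole pipeline can be exercised and calibrated without access to
    controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
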