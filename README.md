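# eqtlenrich

Tumor cis-eQTL scanning with molecular-covariate adjustment, and
GWAS-signal enrichment testing for regulator target-gene sets.

## What problem this solves

Risk variants found by genome-wide association studies (GWAS) of cancers
such as high-grade serous ovarian cancer are overwhelmingly non-coding:
the working model is that they act by tuning the expression of nearby
genes, and that the regulators they point at spread risk through their
downstream targets.  Testing that model in tumors has two statistical
obstacles this package addresses:

1. **Somatic noise drowns the germline signal.**  In tumors, somatic
   copy-number change and CpG methylation dominate expression variation,
   so a cis-eQTL scan must first adjust expression per gene:

   *y<sub>g</sub> = α + β<sub>c</sub>·CN<sub>g</sub> + β<sub>m</sub>·M<sub>g</sub> + ε*,

   keeping the residuals as the trait.  The scan then expands each risk
   locus to its LD proxies (r² > 0.7), pairs every retained SNP with
   every gene within ±250 kb, applies a Wald test
   (t = β̂/SE, Student t<sub>n−2</sub>) per pair, and controls the
   family with Benjamini–Hochberg FDR, calling q ≤ 0.1.  A variance
   decomposition reports the share of expression variance explained by
   each layer (copy number, methylation, cis genotype) as sequential
   incremental R², degrees-of-freedom adjusted.

2. **Is a regulator's target set collectively associated with risk?**
   Targets are selected from a differential-expression table
   (FDR < 0.1, |fold change| > 2, regulator excluded), GWAS SNPs
   (MAF > 0.01) are assigned to genes within the gene body ± flank, and
   three tests are run: a two-sample Kolmogorov–Smirnov test of target
   vs background SNP p-values, two-tailed Fisher's exact tests at
   p < 10⁻³/10⁻⁴/10⁻⁵, repeated at flanks of 10/25/50/100 kb, and
   preranked GSEA (genes ranked by −log₁₀ of their best SNP p at
   ±50 kb) with a gene-label permutation null.

All inputs can be generated by the built-in synthetic-data module, which
plants known eQTLs, variance fractions, enriched target genes and DE
passers, so the whole pipeline is testable without access-controlled
cohort data.

## Worked example

```r
library(eqtlenrich)

cfg <- sim_config(seed = 7, n_genes = 60, n_snps = 200, ld_block_size = 5,
                  n_true_eqtls = 10, var_frac_eqtl = 0.05)
gt    <- simulate_genotypes(cfg)
genes <- simulate_genes(cfg)
pr    <- simulate_profiles(gt, genes, cfg)

adj <- adjust_expression(pr$profiles)
variance_decomposition(pr$profiles, gt, pr$truth$eqtls)
#> VarianceDecomposition over 60 genes:
#>   copy number : 14.889%
#>   methylation :  4.159%
#>   cis genotype: 0.9453%

scan <- run_scan(adj, gt, genes, unique(pr$truth$eqtls$snp_id))
head(scan[scan$significant,
          c("locus", "snp_id", "gene_id", "beta", "t_stat", "p_value", "q_value")])
#>      locus   snp_id gene_id  beta t_stat  p_value  q_value
#> 1 snp00108 snp00106  G00033 0.400   6.36 6.54e-10 4.71e-07
#> 2 snp00158 snp00158  G00048 0.414   6.18 1.90e-09 6.84e-07
#> 3 snp00108 snp00109  G00033 0.375   6.09 3.08e-09 7.38e-07
#> 4 snp00108 snp00108  G00033 0.375   5.94 7.21e-09 1.30e-06
#> 5 snp00035 snp00031  G00011 0.819   5.82 1.37e-08 1.97e-06
#> 6 snp00158 snp00160  G00048 0.383   5.55 5.87e-08 7.04e-06
```

The decomposition recovers the planted layer shares (14% copy number,
4.1% methylation; the cis share is 10 genes planted at 5% each averaged
over 60 genes ≈ 0.9%), and the scan's top calls are the planted
SNP–gene pairs and their LD proxies, with q-values far below the 0.1
calling threshold.

Enrichment of a target-gene set against simulated GWAS summary
statistics:

```r
targets <- pr$truth$eqtls$gene_id
gwas <- simulate_gwas(simulate_snp_grid(5000, 300, cfg), genes, targets, cfg)
enrichment_suite(gwas, genes, targets, n_perm = 1000, seed = 1)
#> Enrichment suite
#>    flank n_target_snps n_background_snps  ks_D      ks_p fisher_or_1e-03 ...
#> 1  10000           950              4034 0.483 2.23e-308            3.32
#> 2  25000          1699              3301 0.595 2.23e-308            5.74
#> 3  50000          2585              2415 0.820 2.23e-308          252.08
#> 4 100000          4249               751 0.514 2.23e-308          231.44
#> GSEA (flank 50000 bp, 60 genes ranked): ES = 0.496, p = 0.03896 (1000 permutations)
```

SNPs near target genes carry inflated association signal, so the K–S
distance is large at every flank, the Fisher odds ratios at p < 10⁻³
are far above 1, and the target set concentrates at the top of the GSEA
ranking.

`run_pipeline(pipeline_config(...))` wires simulate → adjust → scan →
enrich together, writing per-stage TSVs/JSON, a human-readable summary
and a `manifest.json` of MD5 hashes; reruns with the same config and
seed are byte-identical.  A thin command-line wrapper with
`simulate/adjust/eqtl/enrich/run` subcommands lives in
`inst/scripts/eqtlenrich.R`.

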