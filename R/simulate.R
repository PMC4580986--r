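# Synthetic-data generators.  Every generator is a pure function of
# (config, seed): the same configuration always yields the same data, and
# the caller's RNG stream is left untouched.  Defaults emulate the study
# conditions the pipeline was designed for: 339 tumor samples, copy number
# explaining ~14% of expression variance, methylation ~4.1% and the cis
# genotype ~0.25%, genotypes with block LD so that r^2 > 0.7 proxies exist,
# and GWAS p-values uniform away from planted target genes.

#' Simulation configuration
#'
#' @param seed Integer seed; the single source of randomness for all
#'   generators (per-stage substreams are derived from it).
#' @param n_samples Number of samples (default 339, a tumor cohort of
#'   European ancestry after ancestry filtering).
#' @param n_genes,n_snps Genome size of the simulation.
#' @param maf_range Interval within \[0.05, 0.5\] from which SNP minor
#'   allele frequencies are drawn.
#' @param ld_block_size SNPs per LD block; `n_snps` must be divisible by it.
#' @param ld_rho Latent within-block correlation of the Gaussian copula in
#'   \[0, 1\].  Thresholding attenuates correlation, so the default 0.98 is
#'   what it takes for within-block dosage r^2 to typically exceed 0.7,
#'   i.e. for proxy expansion to have material effect.
#' @param var_frac_cn,var_frac_meth Per-gene fraction of expression variance
#'   contributed by copy number (default 0.14) and methylation (0.041).
#' @param var_frac_eqtl Per-gene fraction of expression variance contributed
#'   by the cis genotype of each planted eQTL gene (default 0.0025).
#' @param n_true_eqtls Number of genes with a planted cis-eQTL (default: all
#'   genes, so the genome-wide average cis contribution equals
#'   `var_frac_eqtl`).
#' @param enrichment_noncentrality Mean of the association z-score for GWAS
#'   SNPs inside target-gene windows (0 = global null).
#' @param n_target_genes Number of planted target genes for the GWAS
#'   enrichment component.
#' @param gene_length,gene_spacing Gene body length and start-to-start
#'   spacing in bp (genes are laid on one chromosome at fixed spacing).
#' @param snp_spacing SNP spacing in bp; `NULL` (default) spreads the SNPs
#'   evenly across the span of the gene layout so every gene has cis SNPs.
#' @param chrom Chromosome name used throughout.
#' @return Object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 339L,
                       n_genes = 200L,
                       n_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10L,
                       ld_rho = 0.98,
                       var_frac_cn = 0.14,
                       var_frac_meth = 0.041,
                       var_frac_eqtl = 0.0025,
                       n_true_eqtls = n_genes,
                       enrichment_noncentrality = 3,
                       n_target_genes = 100L,
                       gene_length = 10000L,
                       gene_spacing = 25000L,
                       snp_spacing = NULL,
                       chrom = "1") {
  fr <- c(var_frac_cn, var_frac_meth, var_frac_eqtl)
  if (any(fr < 0) || sum(fr) >= 1) {
    stopf("variance fractions must be >= 0 and sum to < 1")
  }
  if (ld_rho < 0 || ld_rho > 1) stopf("ld_rho must lie in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2]) {
    stopf("maf_range must be an interval")
  }
  if (maf_range[1] < 0.05 || maf_range[2] > 0.5) {
    stopf("maf_range must lie within [0.05, 0.5]")
  }
  if (!is_count(n_true_eqtls)) stopf("n_true_eqtls must be a count")
  if (is.null(snp_spacing)) {
    span <- n_genes * gene_spacing
    snp_spacing <- max(500L, as.integer(ceiling(span / n_snps)))
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), n_snps = as.integer(n_snps),
                 maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho, var_frac_cn = var_frac_cn,
                 var_frac_meth = var_frac_meth, var_frac_eqtl = var_frac_eqtl,
                 n_true_eqtls = as.integer(n_true_eqtls),
                 enrichment_noncentrality = enrichment_noncentrality,
                 n_target_genes = as.integer(n_target_genes),
                 gene_length = as.integer(gene_length),
                 gene_spacing = as.integer(gene_spacing),
                 snp_spacing = as.integer(snp_spacing),
                 chrom = as.character(chrom)),
            class = "SimConfig")
}

#' Deterministic gene layout
#'
#' Lays `n_genes` gene bodies on one chromosome at fixed spacing
#' (0-based half-open coordinates).  No randomness is involved.
#'
#' @param config A [sim_config()].
#' @return Gene annotation `data.frame`.
#' @export
simulate_genes <- function(config) {
  n <- config$n_genes
  start <- (seq_len(n) - 1) * config$gene_spacing
  as_gene_table(data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = config$chrom,
    start = start,
    end = start + config$gene_length,
    strand = "+",
    stringsAsFactors = FALSE))
}

#' Simulate genotypes with block LD
#'
#' SNPs are laid on one chromosome at fixed spacing.  Within a block of
#' `ld_block_size` SNPs, haplotypes come from a latent Gaussian copula with
#' equicorrelation `ld_rho`, thresholded at each SNP's allele frequency;
#' blocks are mutually independent.  Hard calls in \{0, 1, 2\} result.
#'
#' @param config A [sim_config()].
#' @param seed Seed override; defaults to the config seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  n <- config$n_samples
  m <- config$n_snps
  bs <- config$ld_block_size
  if (m %% bs != 0) stopf("n_snps (%d) must be divisible by ld_block_size (%d)",
                          m, bs)
  nb <- m %/% bs
  rho <- config$ld_rho
  with_seed(derive_seed(seed, 1), {
    block <- rep(seq_len(nb), each = bs)
    # proxies within an LD block share their allele frequency, as strongly
    # correlated variants do in real panels; without this the thresholded
    # copula cannot reach high dosage r^2 at any latent correlation
    maf <- stats::runif(nb, config$maf_range[1], config$maf_range[2])[block]
    thr <- stats::qnorm(maf)
    dos <- matrix(0, n, m)
    for (h in 1:2) {
      u <- matrix(stats::rnorm(n * nb), n, nb)
      e <- matrix(stats::rnorm(n * m), n, m)
      z <- sqrt(rho) * u[, block, drop = FALSE] + sqrt(1 - rho) * e
      dos <- dos + (z <= matrix(thr, n, m, byrow = TRUE))
    }
    snps <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chrom = config$chrom,
      pos = 1L + (seq_len(m) - 1L) * config$snp_spacing,
      ref_allele = "A", alt_allele = "G",
      maf = maf, stringsAsFactors = FALSE)
    rownames(dos) <- sprintf("S%04d", seq_len(n))
    genotype_matrix(dos, snps)
  })
}

#' Simulate matched molecular profiles with planted structure
#'
#' For each gene, expression is a linear combination of a discrete
#' copy-number track (states -1/0/+1), a Beta-distributed methylation track
#' and, for planted eQTL genes, the dosage of a cis SNP within 250 kb, plus
#' Gaussian noise.  Coefficients are scaled against the empirical covariate
#' variances so each layer contributes its configured fraction of unit
#' expression variance; realized fractions are recorded in the truth table.
#'
#' @param genotypes A [genotype_matrix()] providing cis dosages.
#' @param genes Gene annotation table.
#' @param config A [sim_config()].
#' @param seed Seed override; defaults to the config seed.
#' @return List with elements `profiles` ([molecular_profiles()]) and
#'   `truth` (list: `eqtls` data.frame of planted (snp_id, gene_id, beta),
#'   `realized` per-gene realized variance fractions).
#' @export
simulate_profiles <- function(genotypes, genes, config, seed = config$seed) {
  genes <- as_gene_table(genes)
  if (nrow(genes) == 0) stopf("genes must be non-empty")
  n_true <- config$n_true_eqtls
  if (n_true > nrow(genes)) {
    stopf("n_true_eqtls (%d) exceeds number of genes (%d)", n_true, nrow(genes))
  }
  n <- config$n_samples
  if (n != nrow(genotypes$dosages)) {
    stopf("config n_samples (%d) does not match genotype matrix (%d samples)",
          n, nrow(genotypes$dosages))
  }
  pos0 <- snp_pos0(genotypes$snps)
  with_seed(derive_seed(seed, 2), {
    ng <- nrow(genes)
    planted <- sort(sample.int(ng, n_true))
    # nearest SNP to each planted gene's midpoint, required within 250 kb
    mid <- (genes$start + genes$end) / 2
    cis_snp <- rep(NA_integer_, ng)
    for (g in planted) {
      same <- which(genotypes$snps$chrom == genes$chrom[g])
      if (!length(same)) stopf("no SNP on chromosome of gene %s", genes$gene_id[g])
      d <- abs(pos0[same] - mid[g])
      j <- same[which.min(d)]
      if (min(d) > 250000) {
        stopf("no SNP within 250 kb of planted gene %s", genes$gene_id[g])
      }
      cis_snp[g] <- j
    }
    expr <- matrix(NA_real_, n, ng)
    cn <- matrix(NA_real_, n, ng)
    meth <- matrix(NA_real_, n, ng)
    truth_beta <- rep(NA_real_, ng)
    realized <- matrix(0, ng, 3, dimnames = list(NULL, c("cn", "meth", "eqtl")))
    f_cn <- config$var_frac_cn
    f_me <- config$var_frac_meth
    f_g <- config$var_frac_eqtl
    scale_coef <- function(f, x) {
      v <- stats::var(x)
      if (f <= 0 || v <= 0) 0 else sqrt(f / v)
    }
    for (g in seq_len(ng)) {
      cn_g <- sample(c(-1, 0, 1), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      me_g <- stats::rbeta(n, 2, 5)
      b_cn <- scale_coef(f_cn, cn_g)
      b_me <- scale_coef(f_me, me_g)
      f_g_gene <- if (g %in% planted) f_g else 0
      x_g <- if (g %in% planted) genotypes$dosages[, cis_snp[g]] else numeric(n)
      b_g <- if (f_g_gene > 0) scale_coef(f_g_gene, x_g) else 0
      used_g <- if (b_g > 0) f_g_gene else 0
      used_cn <- if (b_cn > 0) f_cn else 0
      used_me <- if (b_me > 0) f_me else 0
      sd_eps <- sqrt(max(1 - used_cn - used_me - used_g, 0))
      y <- b_cn * cn_g + b_me * me_g +
        (if (b_g > 0) b_g * x_g else 0) +
        stats::rnorm(n, 0, sd_eps)
      expr[, g] <- y
      cn[, g] <- cn_g
      meth[, g] <- me_g
      v_y <- stats::var(y)
      realized[g, ] <- c(b_cn^2 * stats::var(cn_g),
                         b_me^2 * stats::var(me_g),
                         if (b_g > 0) b_g^2 * stats::var(x_g) else 0) / v_y
      if (g %in% planted) truth_beta[g] <- b_g
    }
    ids <- list(genotypes$sample_ids, genes$gene_id)
    dimnames(expr) <- ids; dimnames(cn) <- ids; dimnames(meth) <- ids
    profiles <- molecular_profiles(expr, cn, meth)
    truth <- list(
      eqtls = data.frame(
        snp_id = genotypes$snps$snp_id[cis_snp[planted]],
        gene_id = genes$gene_id[planted],
        beta = truth_beta[planted],
        stringsAsFactors = FALSE),
      realized = data.frame(gene_id = genes$gene_id,
                            frac_cn = realized[, "cn"],
                            frac_meth = realized[, "meth"],
                            frac_eqtl = realized[, "eqtl"],
                            stringsAsFactors = FALSE))
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate GWAS summary statistics with planted target enrichment
#'
#' SNPs outside every target-gene window receive p ~ Uniform(0, 1); SNPs
#' within a target gene +/- `flank` receive the two-sided normal tail
#' probability of |Z| with Z ~ Normal(`enrichment_noncentrality`, 1), so a
#' noncentrality of 0 reproduces the global null.
#'
#' @param snps SNP metadata `data.frame` (columns `snp_id`, `chrom`, `pos`,
#'   `maf`).
#' @param genes Gene annotation table.
#' @param targets Target gene ids (character vector or [gene_set()]).
#' @param config A [sim_config()].
#' @param flank Window half-width in bp around target genes (default 50 kb).
#' @param seed Seed override; defaults to the config seed.
#' @return GWAS summary `data.frame` sorted by (chrom, pos).
#' @export
simulate_gwas <- function(snps, genes, targets, config, flank = 50000,
                          seed = config$seed) {
  genes <- as_gene_table(genes)
  targets <- as_gene_ids(targets)
  if (!all(targets %in% genes$gene_id)) {
    stopf("targets not present in gene annotation: %s",
          paste(setdiff(targets, genes$gene_id)[1:3], collapse = ", "))
  }
  tg <- genes[genes$gene_id %in% targets, , drop = FALSE]
  pos0 <- snps$pos - 1
  in_window <- rep(FALSE, nrow(snps))
  for (ch in unique(tg$chrom)) {
    sel <- which(snps$chrom == ch)
    if (!length(sel)) next
    g <- tg[tg$chrom == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos0[sel], width = 1L),
      IRanges::IRanges(start = g$start - flank, end = g$end + flank - 1L))
    in_window[sel[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  ncp <- config$enrichment_noncentrality
  with_seed(derive_seed(seed, 3), {
    p <- stats::runif(nrow(snps))
    k <- sum(in_window)
    if (k > 0 && ncp > 0) {
      z <- stats::rnorm(k, mean = ncp, sd = 1)
      p[in_window] <- 2 * stats::pnorm(-abs(z))
    }
    out <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                      pos = snps$pos, maf = snps$maf,
                      p = clamp_p(p), stringsAsFactors = FALSE)
    as_gwas_table(out)
  })
}

#' Simulate a SNP metadata grid (no genotypes)
#'
#' Convenience panel for the GWAS enrichment component, which consumes only
#' SNP positions, frequencies and p-values: `n_snps` SNPs at fixed spacing
#' with MAF drawn from `maf_range`.
#'
#' @param n_snps Number of SNPs.
#' @param spacing Spacing in bp.
#' @param config A [sim_config()] supplying `chrom`, `maf_range` and seed.
#' @param seed Seed override.
#' @return SNP metadata `data.frame`.
#' @export
simulate_snp_grid <- function(n_snps, spacing, config, seed = config$seed) {
  with_seed(derive_seed(seed, 6), {
    data.frame(
      snp_id = sprintf("gsnp%06d", seq_len(n_snps)),
      chrom = config$chrom,
      pos = 1L + (seq_len(n_snps) - 1L) * as.integer(spacing),
      ref_allele = "A", alt_allele = "G",
      maf = stats::runif(n_snps, config$maf_range[1], config$maf_range[2]),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a differential-expression table with planted passers
#'
#' Exactly `n_true` genes pass the joint criterion |fold change| > 2 and
#' FDR < 0.1; every other gene fails at least one of the two.
#'
#' @param genes Gene annotation table.
#' @param n_true Number of planted passers.
#' @param config A [sim_config()].
#' @param true_genes Optional explicit gene ids to plant; defaults to a
#'   random draw of `n_true` genes.
#' @param seed Seed override.
#' @return List with elements `de` (DE table) and `truth` (planted ids).
#' @export
simulate_de_table <- function(genes, n_true, config, true_genes = NULL,
                              seed = config$seed) {
  genes <- as_gene_table(genes)
  ng <- nrow(genes)
  if (n_true > ng) stopf("n_true (%d) exceeds number of genes (%d)", n_true, ng)
  with_seed(derive_seed(seed, 4), {
    if (is.null(true_genes)) {
      true_genes <- genes$gene_id[sort(sample.int(ng, n_true))]
    } else {
      true_genes <- as_gene_ids(true_genes)
      if (length(true_genes) != n_true || !all(true_genes %in% genes$gene_id)) {
        stopf("true_genes must be %d ids present in the annotation", n_true)
      }
    }
    is_true <- genes$gene_id %in% true_genes
    fc <- numeric(ng)
    fdr <- numeric(ng)
    sign <- sample(c(-1, 1), ng, replace = TRUE)
    # passers: clearly beyond both cutoffs
    fc[is_true] <- sign[is_true] * stats::runif(sum(is_true), 2.2, 8)
    fdr[is_true] <- stats::runif(sum(is_true), 0, 0.09)
    # non-passers fail fold change, FDR, or both
    nf <- sum(!is_true)
    mode <- sample(1:3, nf, replace = TRUE)
    fc_f <- sign[!is_true] * stats::runif(nf, 0.1, 1.9)
    fc_p <- sign[!is_true] * stats::runif(nf, 2.2, 8)
    fdr_f <- stats::runif(nf, 0.12, 1)
    fdr_p <- stats::runif(nf, 0, 0.09)
    fc[!is_true] <- ifelse(mode %in% c(1, 3), fc_f, fc_p)
    fdr[!is_true] <- ifelse(mode %in% c(2, 3), fdr_f, fdr_p)
    de <- as_de_table(data.frame(gene_id = genes$gene_id, fold_change = fc,
                                 fdr = fdr, stringsAsFactors = FALSE))
    list(de = de, truth = true_genes)
  })
}

#' Simulate a complete input bundle
#'
#' Generates every pipeline input with shared planted truth: genotypes,
#' gene annotations, molecular profiles with planted cis-eQTLs, a dense
#' GWAS SNP panel with signal concentrated near the planted target genes,
#' and a DE table whose passers are exactly those target genes.
#'
#' @param config A [sim_config()].
#' @param n_gwas_snps Size of the dense GWAS SNP panel (default 20000).
#' @param out_dir Optional directory; when given, all inputs are written
#'   (VCF, BED, TSVs and a truth JSON).
#' @return List: `genotypes`, `genes`, `profiles`, `gwas`, `de`, `truth`.
#' @export
simulate_bundle <- function(config, n_gwas_snps = 20000L, out_dir = NULL) {
  genotypes <- simulate_genotypes(config)
  genes <- simulate_genes(config)
  prof <- simulate_profiles(genotypes, genes, config)
  n_targ <- min(config$n_target_genes, nrow(genes))
  targets <- with_seed(derive_seed(config$seed, 5),
                       sort(sample(genes$gene_id, n_targ)))
  span <- max(genes$end) + 100000
  grid <- simulate_snp_grid(n_gwas_snps,
                            spacing = max(100L, as.integer(span / n_gwas_snps)),
                            config)
  gwas <- simulate_gwas(grid, genes, targets, config)
  de <- simulate_de_table(genes, n_targ, config, true_genes = targets)
  truth <- c(prof$truth, list(targets = targets))
  bundle <- list(genotypes = genotypes, genes = genes,
                 profiles = prof$profiles, gwas = gwas, de = de$de,
                 truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(genotypes, file.path(out_dir, "genotypes.vcf"))
    write_gene_annotations(genes, file.path(out_dir, "genes.bed"))
    write_profiles(prof$profiles, out_dir)
    write_gwas_summary(gwas, file.path(out_dir, "gwas.tsv"))
    write_de_table(de$de, file.path(out_dir, "de.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  bundle
}
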