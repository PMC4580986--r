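# LD proxies, cis windows, Wald association tests, BH FDR and the scan.

test_that("a SNP is always its own proxy with r-squared 1", {
  gm <- tiny_genotypes(n = 40, m = 4)
  ps <- find_proxies(gm, "snp01")
  expect_true("snp01" %in% ps$members$snp_id)
  expect_equal(ps$members$r2[ps$members$snp_id == "snp01"], 1)
  expect_true(all(diff(ps$members$r2) <= 0))
})

test_that("an affine dosage relationship gives r-squared exactly 1", {
  x <- c(0, 1, 2, 0)
  y <- c(0, 2, 4, 0) / 2
  dos <- cbind(x, y)
  rownames(dos) <- sprintf("S%d", 1:4)
  gm <- genotype_matrix(dos, data.frame(
    snp_id = c("a", "b"), chrom = "1", pos = c(1L, 2L),
    ref_allele = "A", alt_allele = "G", maf = 0.25))
  ps <- find_proxies(gm, "a")
  expect_equal(ps$members$r2, c(1, 1))
})

test_that("a monomorphic index SNP is an error", {
  set.seed(19)
  dos <- cbind(rep(1, 10), rbinom(10, 2, 0.5))
  gm <- genotype_matrix(dos, data.frame(
    snp_id = c("mono", "poly"), chrom = "1", pos = c(1L, 2L),
    ref_allele = "A", alt_allele = "G", maf = c(0, 0.5)))
  expect_error(find_proxies(gm, "mono"), "monomorphic")
})

test_that("independent SNPs have near-zero r-squared at large n", {
  set.seed(20)
  n <- 10000
  dos <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))
  gm <- genotype_matrix(dos, data.frame(
    snp_id = c("a", "b"), chrom = "1", pos = c(1L, 2L),
    ref_allele = "A", alt_allele = "G", maf = 0.3))
  ps <- find_proxies(gm, "a", r2_threshold = 0)
  expect_lt(ps$members$r2[ps$members$snp_id == "b"], 0.01)
})

test_that("cis window boundaries follow the half-open convention", {
  snp <- data.frame(chrom = "1", pos = 500001L)  # pos0 = 500000
  genes <- data.frame(gene_id = c("in", "out"), chrom = "1",
                      start = c(740000, 750001), end = c(760000, 760000))
  got <- cis_genes(snp, genes, window = 250000)
  expect_equal(got$gene_id, "in")

  overlapping <- data.frame(gene_id = "on", chrom = "1",
                            start = 499000, end = 501000)
  expect_equal(nrow(cis_genes(snp, overlapping, window = 0)), 1L)
  off <- data.frame(gene_id = "off", chrom = "1", start = 500001, end = 501000)
  expect_equal(nrow(cis_genes(snp, off, window = 0)), 0L)
})

test_that("the Wald test matches the normal-equations + t-CDF oracle", {
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0.1, 1.1, 1.9, -0.1, 0.9, 2.1)
  got <- test_association(x, y, min_complete = 6)
  want <- oracle_ols(x, y)
  expect_equal(got$beta, want$beta, tolerance = 1e-10)
  expect_equal(got$t_stat, want$t_stat, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)

  set.seed(21)
  for (i in 1:5) {
    xi <- rbinom(25, 2, 0.4)
    yi <- 0.3 * xi + rnorm(25)
    got <- test_association(xi, yi)
    want <- oracle_ols(xi, yi)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("a perfect association underflows toward zero, never to zero", {
  x <- rep(c(0, 1, 2), 4)
  got <- test_association(x, x)
  expect_lt(got$p_value, 1e-12)
  expect_gt(got$p_value, 0)
})

test_that("the Wald p is invariant to affine rescaling of either variable", {
  set.seed(22)
  x <- rbinom(30, 2, 0.3)
  y <- 0.5 * x + rnorm(30)
  p0 <- test_association(x, y)$p_value
  expect_equal(test_association(2 * x + 1, y)$p_value, p0, tolerance = 1e-12)
  expect_equal(test_association(x, -3 * y + 10)$p_value, p0, tolerance = 1e-12)
})

test_that("constant dosage is flagged untestable", {
  got <- test_association(rep(1, 12), rnorm(12))
  expect_false(got$testable)
  expect_true(is.na(got$p_value))
})

test_that("permutation of sample labels yields uniform Wald p-values", {
  set.seed(23)
  x <- rbinom(30, 2, 0.4)
  y <- rnorm(30)
  p <- replicate(1000, test_association(x, sample(y))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("bh_fdr reproduces the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(24)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # invariance to input permutation (up to reordering)
  p <- runif(20)
  o <- sample(20)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

scan_fixture <- function(seed = 30) {
  cfg <- sim_config(seed = seed, n_samples = 80, n_genes = 30, n_snps = 30,
                    ld_block_size = 5, n_true_eqtls = 3, var_frac_eqtl = 0.2)
  gt <- simulate_genotypes(cfg)
  genes <- simulate_genes(cfg)
  pr <- simulate_profiles(gt, genes, cfg)
  adj <- adjust_expression(pr$profiles)
  list(cfg = cfg, gt = gt, genes = genes, truth = pr$truth, adj = adj)
}

test_that("run_scan is deterministic and respects the FDR call threshold", {
  fx <- scan_fixture()
  loci <- unique(fx$truth$eqtls$snp_id)
  s1 <- run_scan(fx$adj, fx$gt, fx$genes, loci)
  s2 <- run_scan(fx$adj, fx$gt, fx$genes, loci)
  expect_identical(s1, s2)
  expect_true(all(sign(s1$t_stat) == sign(s1$beta), na.rm = TRUE))
  s0 <- run_scan(fx$adj, fx$gt, fx$genes, loci, fdr_call_threshold = 0)
  expect_equal(sum(s0$significant), 0L)
  # exactly one best pair per locus
  expect_equal(sum(s1$best_in_locus), length(unique(s1$locus)))
})

test_that("enlarging the cis window never removes a tested pair", {
  fx <- scan_fixture(31)
  loci <- unique(fx$truth$eqtls$snp_id)
  small <- run_scan(fx$adj, fx$gt, fx$genes, loci, window = 100000)
  big <- run_scan(fx$adj, fx$gt, fx$genes, loci, window = 300000)
  key <- function(s) paste(s$snp_id, s$gene_id)
  expect_true(all(key(small) %in% key(big)))
  expect_gte(nrow(big), nrow(small))
})

test_that("unknown loci are rejected", {
  fx <- scan_fixture(32)
  expect_error(run_scan(fx$adj, fx$gt, fx$genes, "nonexistent"), "loci")
})
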