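# Target selection, SNP-to-gene windows and the three enrichment tests.

test_that("select_targets applies strict, sign-symmetric cutoffs", {
  de <- data.frame(
    gene_id = c("up", "down", "at_fdr", "at_fc", "driver", "weak"),
    fold_change = c(2.5, -2.5, 3, 2, 4, 1.5),
    fdr = c(0.05, 0.05, 0.1, 0.05, 0.01, 0.01))
  got <- select_targets(de, exclude = "driver")
  expect_setequal(got$gene_ids, c("up", "down"))
})

test_that("window assignment matches a brute-force double loop", {
  fx <- grid_fixture()
  for (flank in c(0, 10000, 50000)) {
    asn <- map_snps_to_genes(fx$snps, fx$genes, flank = flank)
    want <- oracle_map(fx$snps, fx$genes, flank)
    got_keys <- sort(paste(asn$hits$snp_id, asn$hits$gene_id))
    want_keys <- sort(paste(want$snp_id, want$gene_id))
    expect_identical(got_keys, want_keys)
  }
})

test_that("window boundaries are inclusive on the left, exclusive on the right", {
  genes <- data.frame(gene_id = "g", chrom = "1", start = 100000, end = 105000)
  snps <- data.frame(snp_id = c("edge_in", "edge_out", "right_in", "right_out"),
                     chrom = "1",
                     pos = c(50001, 50000, 155000, 155001),  # pos0 = pos - 1
                     maf = 0.2, p = 0.5)
  asn <- map_snps_to_genes(snps, genes, flank = 50000)
  expect_setequal(asn$hits$snp_id, c("edge_in", "right_in"))
})

test_that("assignment is monotone in flank and order-invariant", {
  fx <- grid_fixture(seed = 41)
  a1 <- map_snps_to_genes(fx$snps, fx$genes, flank = 10000)
  a2 <- map_snps_to_genes(fx$snps, fx$genes, flank = 60000)
  k <- function(a) paste(a$hits$snp_id, a$hits$gene_id)
  expect_true(all(k(a1) %in% k(a2)))
  shuffled <- fx$snps[sample(nrow(fx$snps)), ]
  a3 <- map_snps_to_genes(shuffled, fx$genes, flank = 10000)
  expect_setequal(k(a1), k(a3))
})

test_that("the MAF filter drops rare variants before assignment", {
  genes <- data.frame(gene_id = "g", chrom = "1", start = 0, end = 1000)
  snps <- data.frame(snp_id = c("common", "rare", "boundary"), chrom = "1",
                     pos = c(500, 501, 502), maf = c(0.2, 0.005, 0.01),
                     p = 0.5)
  asn <- map_snps_to_genes(snps, genes, flank = 0, maf_min = 0.01)
  expect_equal(asn$hits$snp_id, "common")  # maf <= 0.01 dropped
})

enrich_fixture <- function(seed = 50, ncp = 3, n_targets = 10) {
  cfg <- sim_config(seed = seed, n_genes = 100, n_snps = 10, ld_block_size = 5,
                    enrichment_noncentrality = ncp, gene_spacing = 20000,
                    gene_length = 8000)
  genes <- simulate_genes(cfg)
  targets <- genes$gene_id[seq_len(n_targets) * 9]
  grid <- simulate_snp_grid(3000, 700, cfg, seed = seed)
  gwas <- simulate_gwas(grid, genes, targets, cfg, seed = seed)
  list(genes = genes, targets = targets, gwas = gwas)
}

test_that("K-S enrichment matches the ECDF grid-scan oracle", {
  fx <- enrich_fixture()
  asn <- map_snps_to_genes(fx$gwas, fx$genes, flank = 50000)
  ks <- ks_enrichment(asn, fx$targets)
  sp <- eqtlenrich:::split_target_background(asn, fx$targets)
  expect_equal(ks$D, oracle_ks_D(sp$target, sp$background), tolerance = 1e-12)

  set.seed(51)
  a <- runif(50)
  b <- runif(35)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(unname(kt$statistic), oracle_ks_D(a, b), tolerance = 1e-12)
})

test_that("disjoint supports give D = 1", {
  genes <- data.frame(gene_id = c("t", "b"), chrom = "1",
                      start = c(0, 10000), end = c(1000, 11000))
  snps <- data.frame(snp_id = sprintf("s%d", 1:6), chrom = "1",
                     pos = c(100, 200, 300, 10100, 10200, 10300),
                     maf = 0.2, p = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8))
  asn <- map_snps_to_genes(snps, genes, flank = 0)
  ks <- ks_enrichment(asn, "t")
  expect_equal(ks$D, 1)
})

test_that("empty target or background samples raise a named error", {
  genes <- data.frame(gene_id = "only", chrom = "1", start = 0, end = 1000)
  snps <- data.frame(snp_id = "s1", chrom = "1", pos = 500, maf = 0.2, p = 0.5)
  asn <- map_snps_to_genes(snps, genes, flank = 0)
  expect_error(ks_enrichment(asn, "none_of_these"), "target")
  expect_error(ks_enrichment(asn, "only"), "background")
})

test_that("two-tailed Fisher matches exhaustive hypergeometric enumeration", {
  expect_equal(oracle_fisher_two_tail(3, 1, 1, 3), 0.4857, tolerance = 1e-4)
  expect_equal(stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               oracle_fisher_two_tail(3, 1, 1, 3), tolerance = 1e-10)
  set.seed(52)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(stats::fisher.test(tab)$p.value,
                 oracle_fisher_two_tail(tab[1, 1], tab[1, 2],
                                        tab[2, 1], tab[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("threshold Fisher reports counts, odds ratios and no-SNPs cells", {
  fx <- enrich_fixture(seed = 53)
  asn <- map_snps_to_genes(fx$gwas, fx$genes, flank = 50000)
  ft <- fisher_threshold_enrichment(asn, fx$targets,
                                    thresholds = c(1e-3, 1e-300))
  expect_equal(nrow(ft), 2L)
  # verify the first threshold against the enumeration oracle
  expect_equal(ft$p_value[1],
               oracle_fisher_two_tail(ft$target_below[1],
                                      ft$target_total[1] - ft$target_below[1],
                                      ft$background_below[1],
                                      ft$background_total[1] - ft$background_below[1]),
               tolerance = 1e-8)
  # nothing can pass p < 1e-300: flagged, p = 1
  expect_true(ft$no_snps[2])
  expect_equal(ft$p_value[2], 1)
  # no-effect table is far from significant
  expect_gt(oracle_fisher_two_tail(50, 50, 50, 50), 0.5)
})

test_that("gene ranking follows the min-p rule with lexicographic ties", {
  genes <- data.frame(gene_id = c("b_gene", "a_gene", "solo"), chrom = "1",
                      start = c(0, 0, 10000), end = c(1000, 1000, 11000))
  snps <- data.frame(snp_id = c("shared", "weak", "strong"), chrom = "1",
                     pos = c(500, 600, 10500), maf = 0.2,
                     p = c(1e-4, 0.5, 1e-6))
  asn <- map_snps_to_genes(snps, genes, flank = 0)
  rk <- rank_genes(asn)
  expect_equal(rk$gene_id, c("solo", "a_gene", "b_gene"))
  expect_equal(rk$score[1], 6)
  expect_equal(rk$score[2], rk$score[3])
  expect_true(all(diff(rk$score) <= 0))
})

test_that("gene ranking matches a brute-force per-gene minimum", {
  fx <- grid_fixture(n_snps = 400, n_genes = 100, seed = 54)
  asn <- map_snps_to_genes(fx$snps, fx$genes, flank = 20000)
  rk <- rank_genes(asn)
  p <- fx$snps$p
  names(p) <- fx$snps$snp_id
  for (i in sample(nrow(rk), 20)) {
    g <- rk$gene_id[i]
    want <- -log10(min(p[asn$hits$snp_id[asn$hits$gene_id == g]]))
    expect_equal(rk$score[i], unname(want))
  }
})

test_that("GSEA extremes behave as expected", {
  rk <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   score = seq(5, 0.25, length.out = 20))
  top <- gsea_preranked(rk, rk$gene_id[1:4], n_perm = 200, seed = 1)
  expect_equal(top$es, 1)
  bottom <- gsea_preranked(rk, rk$gene_id[17:20], n_perm = 200, seed = 1)
  expect_lt(bottom$es, 0)
  expect_gt(top$p, 0)
  expect_gte(top$p, 1 / 201)
})

test_that("the running-sum ES matches a naive step-by-step oracle", {
  set.seed(55)
  for (i in 1:10) {
    N <- 15
    scores <- sort(abs(rnorm(N, 2)), decreasing = TRUE)
    hit <- rep(FALSE, N)
    hit[sample.int(N, 4)] <- TRUE
    got <- eqtlenrich:::gsea_es(scores, which(hit), exponent = 1)
    expect_equal(got, oracle_es(scores, hit), tolerance = 1e-12)
    got0 <- eqtlenrich:::gsea_es(scores, which(hit), exponent = 0)
    expect_equal(got0, oracle_es(scores, hit, exponent = 0), tolerance = 1e-12)
  }
})

test_that("the permutation p converges to the exhaustive null on C(6,2)", {
  rk <- data.frame(gene_id = letters[1:6], score = c(4, 2.5, 1.8, 1.2, 0.7, 0.3))
  targets <- c("b", "e")
  placements <- utils::combn(6, 2)
  es_all <- apply(placements, 2, function(idx) {
    eqtlenrich:::gsea_es(rk$score, sort(idx), exponent = 1)
  })
  obs <- gsea_preranked(rk, targets, n_perm = 50000, seed = 2)
  exact <- if (obs$es >= 0) mean(es_all >= obs$es) else mean(es_all <= obs$es)
  expect_equal(obs$p, exact, tolerance = 0.02)
})

test_that("GSEA invariances: rank transform at exponent 0, rescaling at 1", {
  rk <- data.frame(gene_id = sprintf("g%02d", 1:30),
                   score = sort(rexp(30) + 0.1, decreasing = TRUE))
  targets <- rk$gene_id[c(2, 5, 11, 17)]
  a <- gsea_preranked(rk, targets, n_perm = 100, weight_exponent = 0, seed = 3)
  rk2 <- rk
  rk2$score <- rank(rk2$score) / 10  # strictly monotone transform
  b <- gsea_preranked(rk2, targets, n_perm = 100, weight_exponent = 0, seed = 3)
  expect_equal(a$es, b$es, tolerance = 1e-12)

  c1 <- gsea_preranked(rk, targets, n_perm = 100, weight_exponent = 1, seed = 3)
  rk3 <- rk
  rk3$score <- rk3$score * 7.5
  c2 <- gsea_preranked(rk3, targets, n_perm = 100, weight_exponent = 1, seed = 3)
  expect_equal(c1$es, c2$es, tolerance = 1e-12)
})

test_that("the suite produces one report per flank with GSEA at 50 kb", {
  fx <- enrich_fixture(seed = 56)
  suite <- enrichment_suite(fx$gwas, fx$genes, fx$targets, n_perm = 100,
                            seed = 4)
  tab <- enrichment_table(suite)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$flank, c(10000, 25000, 50000, 100000))
  expect_true(all(c("ks_D", "ks_p", "fisher_p_1e-03", "fisher_p_1e-05")
                  %in% names(tab)))
  expect_equal(suite$gsea$flank, 50000)
  expect_gt(suite$gsea$p, 0)
})

test_that("shared SNPs follow the overlap policy", {
  genes <- data.frame(gene_id = c("target", "other"), chrom = "1",
                      start = c(0, 500), end = c(1000, 1500))
  snps <- data.frame(snp_id = c("shared", "t_only", "o_only"), chrom = "1",
                     pos = c(700, 100, 1400), maf = 0.2, p = c(0.1, 0.2, 0.3))
  asn <- map_snps_to_genes(snps, genes, flank = 0)
  sp <- eqtlenrich:::split_target_background(asn, "target")
  expect_equal(sort(sp$target), c(0.1, 0.2))
  expect_equal(sp$background, 0.3)
  sp2 <- eqtlenrich:::split_target_background(asn, "target", "drop-shared")
  expect_equal(sp2$target, 0.2)
})
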