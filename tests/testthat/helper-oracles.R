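# Independent brute-force oracles used to cross-check the package's
# implementations on small fixtures.  These deliberately avoid the code
# paths they verify: explicit normal equations instead of lm.fit, grid
# scans instead of ks.test, exhaustive enumeration instead of closed forms.

# Simple linear regression by explicit normal equations + t CDF.
oracle_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  xtx <- t(X) %*% X
  coef <- solve(xtx, t(X) %*% y)
  res <- y - X %*% coef
  s2 <- sum(res^2) / (n - 2)
  vcov <- s2 * solve(xtx)
  beta <- coef[2]
  se <- sqrt(vcov[2, 2])
  t_stat <- beta / se
  list(beta = beta, t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

# Multiple regression residuals by explicit normal equations.
oracle_residuals <- function(X, y) {
  as.vector(y - X %*% solve(t(X) %*% X, t(X) %*% y))
}

# Benjamini-Hochberg step-up formula computed literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sample K-S statistic by scanning every observed value.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# Two-tailed Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins.
oracle_fisher_two_tail <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Window assignment by double loop over SNPs and genes.
oracle_map <- function(snps, genes, flank, maf_min = 0.01) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    if (is.na(snps$maf[i]) || snps$maf[i] <= maf_min) next
    pos0 <- snps$pos[i] - 1
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] != genes$chrom[j]) next
      if (pos0 >= genes$start[j] - flank && pos0 < genes$end[j] + flank) {
        out[[length(out) + 1]] <- data.frame(snp_id = snps$snp_id[i],
                                             gene_id = genes$gene_id[j],
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(snp_id = character(), gene_id = character()))
  }
  do.call(rbind, out)
}

# Running-sum enrichment score computed naively step by step.
oracle_es <- function(scores, hit, exponent = 1) {
  N <- length(scores)
  w <- abs(scores)^exponent
  nr <- sum(w[hit])
  running <- 0
  extremum <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      running <- running + (if (nr > 0) w[i] / nr else 1 / sum(hit))
    } else {
      running <- running - 1 / (N - sum(hit))
    }
    if (abs(running) > abs(extremum)) extremum <- running
  }
  extremum
}

# canonical small fixtures -------------------------------------------------

tiny_profiles <- function(n = 30, ng = 3, seed = 42) {
  set.seed(seed)
  cn <- matrix(sample(c(-1, 0, 1), n * ng, replace = TRUE), n, ng)
  me <- matrix(stats::rbeta(n * ng, 2, 5), n, ng)
  ex <- 0.8 * cn + 1.5 * me + matrix(stats::rnorm(n * ng), n, ng)
  ids <- list(sprintf("S%03d", 1:n), sprintf("G%03d", 1:ng))
  dimnames(ex) <- ids; dimnames(cn) <- ids; dimnames(me) <- ids
  molecular_profiles(ex, cn, me)
}

tiny_genotypes <- function(n = 30, m = 4, seed = 43, maf = 0.3) {
  set.seed(seed)
  dos <- matrix(stats::rbinom(n * m, 2, maf), n, m)
  rownames(dos) <- sprintf("S%03d", 1:n)
  genotype_matrix(dos, data.frame(
    snp_id = sprintf("snp%02d", 1:m), chrom = "1",
    pos = 1000L * (1:m), ref_allele = "A", alt_allele = "G",
    maf = maf, stringsAsFactors = FALSE))
}

grid_fixture <- function(n_snps = 500, n_genes = 50, seed = 40) {
  set.seed(seed)
  snps <- data.frame(snp_id = sprintf("rs%04d", 1:n_snps),
                     chrom = sample(c("1", "2"), n_snps, replace = TRUE),
                     pos = sample.int(2e6, n_snps),
                     maf = runif(n_snps, 0, 0.5),
                     p = runif(n_snps), stringsAsFactors = FALSE)
  start <- sample.int(2e6 - 20000, n_genes)
  genes <- data.frame(gene_id = sprintf("G%03d", 1:n_genes),
                      chrom = sample(c("1", "2"), n_genes, replace = TRUE),
                      start = start, end = start + sample(1000:20000, n_genes,
                                                          replace = TRUE),
                      stringsAsFactors = FALSE)
  list(snps = snps, genes = genes)
}
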