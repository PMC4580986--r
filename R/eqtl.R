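# Cis-eQTL association scan on adjusted expression: LD-proxy expansion,
# cis window definition, per-pair Wald tests and Benjamini-Hochberg FDR.

#' Find LD proxies of an index SNP
#'
#' r-squared is the squared Pearson correlation of dosage vectors over the
#' samples non-missing in both SNPs.  Members with r-squared strictly above
#' `r2_threshold` are returned sorted by descending r-squared; the index
#' SNP is always a member with r-squared 1.
#'
#' @param panel A [genotype_matrix()] (e.g. a reference LD panel).
#' @param index_snp SNP id present in the panel.
#' @param r2_threshold Minimum r-squared, exclusive (default 0.7).
#' @return Object of class `ProxySet`: list with `index_snp` and `members`
#'   (`data.frame` of `snp_id`, `r2`).
#' @export
find_proxies <- function(panel, index_snp, r2_threshold = 0.7) {
  j <- match(index_snp, panel$snps$snp_id)
  if (is.na(j)) stopf("index SNP %s not in panel", index_snp)
  x <- panel$dosages[, j]
  if (stats::var(x, na.rm = TRUE) %in% c(0, NA) || all(is.na(x))) {
    stopf("index SNP %s is monomorphic in the panel (r^2 undefined)", index_snp)
  }
  r <- suppressWarnings(
    stats::cor(panel$dosages, x, use = "pairwise.complete.obs"))
  r2 <- as.vector(r)^2
  r2[j] <- 1
  keep <- which(!is.na(r2) & (r2 > r2_threshold | seq_along(r2) == j))
  ord <- keep[order(-r2[keep], panel$snps$snp_id[keep])]
  structure(list(index_snp = index_snp,
                 members = data.frame(snp_id = panel$snps$snp_id[ord],
                                      r2 = r2[ord],
                                      stringsAsFactors = FALSE)),
            class = "ProxySet")
}

#' @export
print.ProxySet <- function(x, ...) {
  cat(sprintf("ProxySet for %s: %d member(s), min r2 = %.3f\n",
              x$index_snp, nrow(x$members), min(x$members$r2)))
  invisible(x)
}

#' Genes in the cis window of a SNP
#'
#' A gene is cis to a SNP when its body (0-based half-open) overlaps
#' `[pos0 - window, pos0 + window + 1)`, where `pos0` is the SNP's internal
#' 0-based position — i.e. genes within `window` bp on either side.
#'
#' @param snp One-row SNP metadata (`chrom`, `pos`) — e.g. a row of
#'   `genotypes$snps`.
#' @param genes Gene annotation table.
#' @param window Half-width in bp (default 250000).
#' @return The overlapping rows of `genes` (possibly zero rows).
#' @export
cis_genes <- function(snp, genes, window = 250000) {
  genes <- as_gene_table(genes)
  pos0 <- snp$pos - 1
  sel <- genes$chrom == snp$chrom &
    genes$start < pos0 + window + 1 &
    genes$end > pos0 - window
  genes[sel, , drop = FALSE]
}

#' Wald test of association between dosage and adjusted expression
#'
#' Ordinary least squares of the residual expression on
#' \[intercept, dosage\]; the Wald statistic is the coefficient divided by
#' its standard error and the two-sided p-value comes from Student's t with
#' `n_used - 2` degrees of freedom.  Incomplete pairs are dropped.
#'
#' @param dosage,residual_expr Per-sample numeric vectors of equal length.
#' @param min_complete Minimum complete pairs (default 10).
#' @return List with `beta`, `t_stat`, `p_value`, `n_used`, `testable`.
#'   A constant dosage yields `testable = FALSE` with `NA` statistics.
#' @export
test_association <- function(dosage, residual_expr, min_complete = 10L) {
  if (length(dosage) != length(residual_expr)) {
    stopf("dosage and expression vectors differ in length")
  }
  ok <- !is.na(dosage) & !is.na(residual_expr)
  n <- sum(ok)
  if (n < min_complete) stopf("need at least %d complete pairs, have %d",
                              min_complete, n)
  x <- dosage[ok]
  y <- residual_expr[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    return(list(beta = NA_real_, t_stat = NA_real_, p_value = NA_real_,
                n_used = n, testable = FALSE))
  }
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - beta * mean(x)
  rss <- sum((y - a - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t_stat <- if (se == 0) sign(beta) * Inf else beta / se
  p <- clamp_p(2 * stats::pt(-abs(t_stat), df = n - 2))
  list(beta = beta, t_stat = t_stat, p_value = p, n_used = n, testable = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up q-values `q_(i) = min_(j>=i) p_(j) * m / j`, clipped to 1 and
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run the cis-eQTL scan around a set of risk loci
#'
#' For each index locus the SNP set is expanded to its LD proxies
#' (r-squared above `r2_threshold` in `proxy_panel`), every retained SNP is
#' paired with every gene within `window` bp, each pair is Wald-tested on
#' the adjusted expression, and BH correction is applied across all tested
#' pairs jointly (`fdr_scope = "global"`; `"per_locus"` corrects within each
#' locus instead).  Missing dosages are mean-imputed per SNP before testing.
#' Within each locus the best pair (smallest p, then largest |t|, then
#' lexicographic snp_id) is flagged `best_in_locus`, mirroring a
#' one-row-per-association report.
#'
#' @param adjusted An [adjust_expression()] result.
#' @param genotypes [genotype_matrix()] of the eQTL cohort.
#' @param genes Gene annotation table.
#' @param loci Character vector of index SNP ids.
#' @param proxy_panel [genotype_matrix()] used for proxy search; defaults
#'   to `genotypes` (the paper-style setup passes a reference panel here).
#' @param r2_threshold Proxy r-squared threshold (default 0.7).
#' @param window Cis window half-width in bp (default 250000).
#' @param fdr_call_threshold Call associations significant at q at or below
#'   this value (default 0.1).
#' @param fdr_scope `"global"` (default) or `"per_locus"` BH family.
#' @return `data.frame` of class `eqtl_results` with one row per tested
#'   pair: `locus`, `snp_id`, `gene_id`, `beta`, `t_stat`, `p_value`,
#'   `q_value`, `n_used`, `significant`, `best_in_locus`.
#' @export
run_scan <- function(adjusted, genotypes, genes, loci,
                     proxy_panel = genotypes,
                     r2_threshold = 0.7, window = 250000,
                     fdr_call_threshold = 0.1,
                     fdr_scope = c("global", "per_locus")) {
  fdr_scope <- match.arg(fdr_scope)
  if (!inherits(adjusted, "AdjustedExpression")) {
    stopf("`adjusted` must come from adjust_expression()")
  }
  genes <- as_gene_table(genes)
  missing_loci <- setdiff(loci, proxy_panel$snps$snp_id)
  if (length(missing_loci)) stopf("loci not in proxy panel: %s",
                                  paste(missing_loci, collapse = ", "))
  # enumerate (locus, snp, gene) candidate pairs
  pairs <- list()
  for (locus in loci) {
    ps <- find_proxies(proxy_panel, locus, r2_threshold)
    snp_ids <- intersect(ps$members$snp_id, genotypes$snps$snp_id)
    for (sid in snp_ids) {
      meta <- genotypes$snps[match(sid, genotypes$snps$snp_id), ]
      cg <- cis_genes(meta, genes, window)
      gids <- intersect(cg$gene_id, adjusted$gene_ids)
      if (length(gids)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          locus = locus, snp_id = sid, gene_id = gids,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pairs)) stopf("no testable SNP-gene pair at any locus")
  pairs <- do.call(rbind, pairs)
  # one test per distinct (snp, gene) pair; first locus keeps attribution
  pairs <- pairs[!duplicated(pairs[c("snp_id", "gene_id")]), , drop = FALSE]
  # analysis-time mean imputation of missing dosages, counted and reported
  dos <- genotypes$dosages[, unique(pairs$snp_id), drop = FALSE]
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    message(sprintf("mean-imputed %d missing dosage call(s)", n_imp))
    dos <- apply(dos, 2, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      x
    })
  }
  np <- nrow(pairs)
  beta <- t_stat <- p <- rep(NA_real_, np)
  n_used <- integer(np)
  testable <- logical(np)
  gidx <- match(pairs$gene_id, adjusted$gene_ids)
  sidx <- match(pairs$snp_id, colnames(dos))
  for (i in seq_len(np)) {
    r <- test_association(dos[, sidx[i]], adjusted$residuals[, gidx[i]])
    beta[i] <- r$beta; t_stat[i] <- r$t_stat; p[i] <- r$p_value
    n_used[i] <- r$n_used; testable[i] <- r$testable
  }
  if (!any(testable)) stopf("no testable SNP-gene pair at any locus")
  q <- rep(NA_real_, np)
  if (fdr_scope == "global") {
    q[testable] <- bh_fdr(p[testable])
  } else {
    for (locus in unique(pairs$locus)) {
      sel <- testable & pairs$locus == locus
      if (any(sel)) q[sel] <- bh_fdr(p[sel])
    }
  }
  out <- data.frame(pairs, beta = beta, t_stat = t_stat, p_value = p,
                    q_value = q, n_used = n_used,
                    significant = !is.na(q) & q <= fdr_call_threshold,
                    best_in_locus = FALSE, stringsAsFactors = FALSE)
  for (locus in unique(out$locus)) {
    sel <- which(testable & out$locus == locus)
    if (!length(sel)) next
    o <- sel[order(out$p_value[sel], -abs(out$t_stat[sel]), out$snp_id[sel])]
    out$best_in_locus[o[1]] <- TRUE
  }
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eqtl_results", "data.frame")
  out
}
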