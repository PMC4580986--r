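# Target-gene selection from differential expression and the three
# GWAS-signal enrichment statistics over window-based SNP-to-gene
# assignments: two-sample K-S, threshold Fisher's exact and preranked
# permutation GSEA.

#' Select target genes from a differential-expression table
#'
#' Keeps genes with `fdr < fdr_max` and `|fold_change| > fold_min` (both
#' strict), then removes `exclude` (typically the perturbed regulator
#' itself).
#'
#' @param de DE table (`gene_id`, `fold_change`, `fdr`).
#' @param fdr_max FDR cutoff, exclusive (default 0.1).
#' @param fold_min Absolute linear fold-change cutoff, exclusive (default 2).
#' @param exclude Gene ids to drop from the result.
#' @param name Name for the resulting set.
#' @return A [gene_set()].
#' @export
select_targets <- function(de, fdr_max = 0.1, fold_min = 2,
                           exclude = character(), name = "targets") {
  de <- as_de_table(de)
  if (nrow(de) == 0) stopf("DE table is empty")
  sel <- de$fdr < fdr_max & abs(de$fold_change) > fold_min
  ids <- setdiff(de$gene_id[sel & !is.na(sel)], as_gene_ids(exclude))
  if (!length(ids)) warnf("no gene passed the selection criteria")
  gene_set(sort(ids), name = name)
}

#' Assign GWAS SNPs to genes by window overlap
#'
#' SNPs with `maf <= maf_min` are dropped first.  A SNP maps to a gene iff
#' its 0-based position lies in `[start - flank, end + flank)`; a SNP may
#' map to several genes.  Overlap is computed with an interval index, so the
#' result is independent of input order.
#'
#' @param snps GWAS summary table (or any SNP table with `snp_id`, `chrom`,
#'   `pos`, `maf`, optionally `p`).
#' @param genes Gene annotation table.
#' @param flank Window half-width in bp (default 50000).
#' @param maf_min Minor-allele-frequency filter, exclusive (default 0.01).
#' @return Object of class `SnpAssignment`: list with `flank`, `snps` (the
#'   retained SNP table) and `hits` (`data.frame` of `snp_id`, `gene_id`).
#' @export
map_snps_to_genes <- function(snps, genes, flank = 50000, maf_min = 0.01) {
  if (flank < 0) stopf("flank must be >= 0")
  genes <- as_gene_table(genes)
  keep <- !is.na(snps$maf) & snps$maf > maf_min
  snps <- snps[keep, , drop = FALSE]
  rownames(snps) <- NULL
  pos0 <- snps$pos - 1
  hits <- vector("list", length(unique(genes$chrom)))
  i <- 0L
  for (ch in unique(genes$chrom)) {
    i <- i + 1L
    g <- genes[genes$chrom == ch, , drop = FALSE]
    sel <- which(snps$chrom == ch)
    if (!length(sel) || !nrow(g)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos0[sel], width = 1L),
      IRanges::IRanges(start = g$start - flank, end = g$end + flank - 1L))
    hits[[i]] <- data.frame(snp_id = snps$snp_id[sel[S4Vectors::queryHits(ov)]],
                            gene_id = g$gene_id[S4Vectors::subjectHits(ov)],
                            stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) hits <- data.frame(snp_id = character(),
                                        gene_id = character(),
                                        stringsAsFactors = FALSE)
  structure(list(flank = flank, snps = snps, hits = hits),
            class = "SnpAssignment")
}

#' @export
print.SnpAssignment <- function(x, ...) {
  cat(sprintf("SnpAssignment (flank %d bp): %d SNPs, %d assigned, %d genes covered\n",
              x$flank, nrow(x$snps), length(unique(x$hits$snp_id)),
              length(unique(x$hits$gene_id))))
  invisible(x)
}

# Split assigned SNP p-values into target-window vs background samples.
# A SNP assigned to both a target and a non-target gene counts as target
# ("target-priority"); "drop-shared" removes such SNPs from both samples.
# Unassigned SNPs are excluded entirely.
split_target_background <- function(assignment, targets,
                                    overlap_policy = c("target-priority",
                                                       "drop-shared")) {
  overlap_policy <- match.arg(overlap_policy)
  targets <- as_gene_ids(targets)
  if (is.null(assignment$snps$p)) stopf("assignment carries no p-values")
  hit_t <- unique(assignment$hits$snp_id[assignment$hits$gene_id %in% targets])
  hit_any <- unique(assignment$hits$snp_id)
  bg_ids <- setdiff(hit_any, hit_t)
  if (overlap_policy == "drop-shared") {
    only_t <- setdiff(hit_t,
                      unique(assignment$hits$snp_id[!(assignment$hits$gene_id %in% targets)]))
    hit_t <- only_t
  }
  p <- assignment$snps$p
  names(p) <- assignment$snps$snp_id
  list(target = unname(p[hit_t]), background = unname(p[bg_ids]))
}

#' Two-sample K-S test of GWAS signal in target-gene windows
#'
#' Compares the p-value distribution of SNPs assigned to at least one
#' target gene against that of SNPs assigned to at least one gene but to no
#' target gene (unassigned SNPs are excluded).  D is the maximum absolute
#' ECDF difference; the p-value uses the asymptotic two-sample K-S
#' distribution.
#'
#' @param assignment A [map_snps_to_genes()] result whose SNP table carries
#'   a `p` column.
#' @param targets Target gene ids or a [gene_set()].
#' @param overlap_policy How SNPs shared between target and non-target
#'   windows are handled (see Details in the package vignette).
#' @return List with `D`, `p`, `n_target`, `n_background`.
#' @export
ks_enrichment <- function(assignment, targets,
                          overlap_policy = c("target-priority", "drop-shared")) {
  sp <- split_target_background(assignment, targets, match.arg(overlap_policy))
  if (!length(sp$target)) stopf("target SNP sample is empty")
  if (!length(sp$background)) stopf("background SNP sample is empty")
  kt <- suppressWarnings(stats::ks.test(sp$target, sp$background,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = clamp_p(kt$p.value),
       n_target = length(sp$target), n_background = length(sp$background))
}

#' Fisher's exact enrichment at fixed p-value thresholds
#'
#' For each threshold t, builds the 2x2 table (target/background) x
#' (p < t / p >= t) and computes the two-tailed Fisher exact p-value by
#' hypergeometric probability-mass summation.  The odds ratio is the sample
#' cross-product ratio, with a Haldane 0.5 correction when any cell is 0.
#' A threshold with no qualifying SNP in either group is flagged `no_snps`
#' with p = 1.
#'
#' @inheritParams ks_enrichment
#' @param thresholds Numeric vector of p-value thresholds
#'   (default `c(1e-3, 1e-4, 1e-5)`).
#' @return `data.frame` with one row per threshold: counts, `odds_ratio`,
#'   `p_value`, `no_snps`.
#' @export
fisher_threshold_enrichment <- function(assignment, targets,
                                        thresholds = c(1e-3, 1e-4, 1e-5),
                                        overlap_policy = c("target-priority",
                                                           "drop-shared")) {
  sp <- split_target_background(assignment, targets, match.arg(overlap_policy))
  if (!length(sp$target)) stopf("target SNP sample is empty")
  if (!length(sp$background)) stopf("background SNP sample is empty")
  out <- lapply(thresholds, function(thr) {
    a <- sum(sp$target < thr)
    b <- length(sp$target) - a
    cc <- sum(sp$background < thr)
    d <- length(sp$background) - cc
    if (a + cc == 0) {
      return(data.frame(threshold = thr, target_below = a, target_total = a + b,
                        background_below = cc, background_total = cc + d,
                        odds_ratio = NA_real_, p_value = 1, no_snps = TRUE))
    }
    m <- matrix(c(a, b, cc, d), nrow = 2)
    pv <- stats::fisher.test(m, alternative = "two.sided")$p.value
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    data.frame(threshold = thr, target_below = a, target_total = a + b,
               background_below = cc, background_total = cc + d,
               odds_ratio = or, p_value = clamp_p(pv), no_snps = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank genes by their strongest assigned GWAS SNP
#'
#' Scores each covered gene by the -log10 of the smallest p-value among its
#' assigned SNPs and returns genes in descending score order (ties broken
#' lexicographically by gene id).  Genes with no assigned SNP are excluded,
#' not scored 0.
#'
#' @param assignment A [map_snps_to_genes()] result whose SNP table carries
#'   a `p` column.
#' @return `data.frame` of class `RankedGenes` with columns `gene_id`,
#'   `score`.
#' @export
rank_genes <- function(assignment) {
  if (is.null(assignment$snps$p)) stopf("assignment carries no p-values")
  p <- assignment$snps$p
  names(p) <- assignment$snps$snp_id
  hp <- p[assignment$hits$snp_id]
  minp <- tapply(hp, assignment$hits$gene_id, min)
  out <- data.frame(gene_id = names(minp),
                    score = -log10(as.numeric(minp)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedGenes", "data.frame")
  out
}

# Enrichment score of one hit-index placement on a ranked score vector.
# scores: full ranked vector (descending); idx: sorted positions of hits.
# Hits increment the running sum by |score|^exponent normalized by the
# set's total; misses decrement by 1/(N - k).  Returns the signed extremum.
gsea_es <- function(scores, idx, exponent = 1) {
  N <- length(scores)
  k <- length(idx)
  if (k == 0 || k >= N) stopf("hit set must be a proper non-empty subset")
  w <- abs(scores[idx])^exponent
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / k else w <- w / nr
  cw <- cumsum(w)
  miss_step <- 1 / (N - k)
  j <- seq_len(k)
  after <- cw - (idx - j) * miss_step
  before <- c(0, cw[-k]) - (idx - j) * miss_step
  mx <- max(after)
  mn <- min(before, 0)
  if (mx >= -mn) mx else mn
}

#' Preranked GSEA with a gene-label permutation null
#'
#' Computes the weighted running-sum enrichment score of a target set on a
#' ranked gene list and assesses it against a null of uniformly random
#' gene-label sets of the same size.  The permutation p-value uses the
#' add-one estimator `(1 + #{perm ES at least as extreme}) / (n_perm + 1)`
#' on the observed ES's own side, so it is never 0.
#'
#' @param ranked A [rank_genes()] result (or data.frame with `gene_id`,
#'   `score`).
#' @param targets Target gene ids or a [gene_set()].
#' @param n_perm Number of permutations (default 10000).
#' @param weight_exponent Score weighting exponent; 1 (default) is the
#'   weighted formulation, 0 the classic Kolmogorov-Smirnov-like one.
#' @param seed Seed for the permutation stream.
#' @return List with `es`, `p`, `n_perm`, `n_hits`.
#' @export
gsea_preranked <- function(ranked, targets, n_perm = 10000,
                           weight_exponent = 1, seed = 1L) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  ranked <- ranked[order(-ranked$score, ranked$gene_id), , drop = FALSE]
  targets <- as_gene_ids(targets)
  idx <- sort(which(ranked$gene_id %in% targets))
  if (!length(idx)) stopf("target set does not intersect the ranked genes")
  N <- nrow(ranked)
  k <- length(idx)
  if (k >= N) stopf("target set covers every ranked gene")
  es <- gsea_es(ranked$score, idx, weight_exponent)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es(ranked$score, sort(sample.int(N, k)), weight_exponent)
    }, numeric(1))
  })
  p <- if (es >= 0) {
    (1 + sum(perm >= es)) / (n_perm + 1)
  } else {
    (1 + sum(perm <= es)) / (n_perm + 1)
  }
  list(es = es, p = p, n_perm = n_perm, n_hits = k)
}

#' Run the full enrichment battery across flank sizes
#'
#' Repeats SNP-to-gene assignment, the K-S test and the threshold Fisher
#' tests at every flank in `flanks`, and runs preranked GSEA once at
#' `gsea_flank` (50 kb by default).
#'
#' @param snps GWAS summary table (with `p`).
#' @param genes Gene annotation table.
#' @param targets Target gene ids or a [gene_set()].
#' @param flanks Flank sizes in bp (default 10, 25, 50, 100 kb).
#' @param thresholds Fisher thresholds (default `c(1e-3, 1e-4, 1e-5)`).
#' @param maf_min MAF filter (default 0.01).
#' @param n_perm GSEA permutations (default 10000).
#' @param gsea_flank Flank used for the GSEA ranking (default 50000).
#' @param weight_exponent GSEA weighting exponent (default 1).
#' @param seed Seed for the GSEA permutation stream.
#' @param overlap_policy See [ks_enrichment()].
#' @return Object of class `EnrichmentSuite`: list with `reports` (one per
#'   flank: `flank`, `ks`, `fisher`, SNP counts), `gsea`, and the
#'   parameters used.  Use [enrichment_table()] for a flat per-flank table.
#' @export
enrichment_suite <- function(snps, genes, targets,
                             flanks = c(10000, 25000, 50000, 100000),
                             thresholds = c(1e-3, 1e-4, 1e-5),
                             maf_min = 0.01, n_perm = 10000,
                             gsea_flank = 50000, weight_exponent = 1,
                             seed = 1L,
                             overlap_policy = c("target-priority",
                                                "drop-shared")) {
  overlap_policy <- match.arg(overlap_policy)
  genes <- as_gene_table(genes)
  targets <- as_gene_ids(targets)
  reports <- lapply(flanks, function(fl) {
    asn <- map_snps_to_genes(snps, genes, flank = fl, maf_min = maf_min)
    ks <- ks_enrichment(asn, targets, overlap_policy)
    fisher <- fisher_threshold_enrichment(asn, targets, thresholds,
                                          overlap_policy)
    list(flank = fl, ks = ks, fisher = fisher,
         n_target_snps = ks$n_target, n_background_snps = ks$n_background)
  })
  asn_g <- map_snps_to_genes(snps, genes, flank = gsea_flank, maf_min = maf_min)
  ranked <- rank_genes(asn_g)
  gsea <- gsea_preranked(ranked, targets, n_perm = n_perm,
                         weight_exponent = weight_exponent, seed = seed)
  gsea$flank <- gsea_flank
  gsea$n_ranked_genes <- nrow(ranked)
  structure(list(reports = reports, gsea = gsea, flanks = flanks,
                 thresholds = thresholds, maf_min = maf_min,
                 overlap_policy = overlap_policy),
            class = "EnrichmentSuite")
}

#' Flatten an enrichment suite into a per-flank table
#'
#' One row per flank with the K-S statistic and p-value and, per Fisher
#' threshold, the odds ratio and p-value (`NA` odds ratio with p = 1 marks
#' a "no SNPs" cell).
#'
#' @param suite An [enrichment_suite()] result.
#' @return `data.frame` with `length(suite$flanks)` rows.
#' @export
enrichment_table <- function(suite) {
  rows <- lapply(suite$reports, function(r) {
    row <- data.frame(flank = r$flank,
                      n_target_snps = r$n_target_snps,
                      n_background_snps = r$n_background_snps,
                      ks_D = r$ks$D, ks_p = r$ks$p)
    for (i in seq_len(nrow(r$fisher))) {
      thr <- r$fisher$threshold[i]
      lab <- format(thr, scientific = TRUE)
      row[[paste0("fisher_or_", lab)]] <- r$fisher$odds_ratio[i]
      row[[paste0("fisher_p_", lab)]] <- r$fisher$p_value[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.EnrichmentSuite <- function(x, ...) {
  cat("Enrichment suite\n")
  print(enrichment_table(x), digits = 3)
  cat(sprintf("GSEA (flank %d bp, %d genes ranked): ES = %.3f, p = %.4g (%d permutations)\n",
              x$gsea$flank, x$gsea$n_ranked_genes, x$gsea$es, x$gsea$p,
              x$gsea$n_perm))
  invisible(x)
}
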