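# Core in-memory containers shared by all pipeline stages.
#
# Conventions:
#   * SNP positions (`pos`) are stored 1-based, as printed in VCF and GWAS
#     summary files; `snp_pos0()` converts to the internal 0-based system.
#   * Gene coordinates are 0-based half-open, i.e. exactly the BED
#     convention, so window arithmetic is overlap-safe.
#   * Missing dosages are NA; they are imputed (per-SNP mean) only at
#     analysis time, never at read time.

#' Construct a genotype matrix
#'
#' Bundles a samples x SNPs alt-allele dosage matrix with per-SNP metadata.
#' Hard calls are 0/1/2; imputed dosages may be any value in \[0, 2\].
#' Missing genotypes are `NA`.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns.  Row
#'   names are sample ids, column names SNP ids.
#' @param snps `data.frame` with columns `snp_id`, `chrom`, `pos` (1-based
#'   bp), `ref_allele`, `alt_allele`, `maf` (folded frequency in \[0, 0.5\]).
#'   `chrom`/`pos` may be `NA` when the source format carries no coordinates.
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosages`, `snps`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.data.frame(snps)) stopf("`snps` must be a data.frame")
  needed <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele", "maf")
  miss <- setdiff(needed, names(snps))
  if (length(miss)) stopf("snp metadata lacks column(s): %s",
                          paste(miss, collapse = ", "))
  snps <- as.data.frame(snps[needed], stringsAsFactors = FALSE)
  if (ncol(dosages) != nrow(snps)) {
    stopf("dosage matrix has %d SNP columns but metadata has %d rows",
          ncol(dosages), nrow(snps))
  }
  if (anyDuplicated(snps$snp_id)) {
    stopf("duplicate snp_id: %s",
          paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- snps$snp_id
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stopf("dosages must lie in [0, 2]; observed range [%g, %g]", rng[1], rng[2])
  }
  bad_maf <- !is.na(snps$maf) & (snps$maf < 0 | snps$maf > 0.5)
  if (any(bad_maf)) stopf("maf outside [0, 0.5] for %s",
                          paste(snps$snp_id[bad_maf], collapse = ", "))
  bad_pos <- !is.na(snps$pos) & snps$pos < 1
  if (any(bad_pos)) stopf("pos must be >= 1 (1-based)")
  structure(list(dosages = dosages, snps = snps,
                 sample_ids = rownames(dosages)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

# 0-based position of each SNP (internal coordinate system)
snp_pos0 <- function(snps) snps$pos - 1

#' Construct matched molecular profiles
#'
#' Aligned samples x genes matrices of expression (log-scale abundance),
#' relative somatic copy number and CpG methylation beta values.  All three
#' matrices must share identical sample and gene orderings.
#'
#' @param expression,copy_number,methylation Numeric matrices with sample
#'   row names and gene column names.
#' @return Object of class `MolecularProfiles`.
#' @export
molecular_profiles <- function(expression, copy_number, methylation) {
  mats <- list(expression = as.matrix(expression),
               copy_number = as.matrix(copy_number),
               methylation = as.matrix(methylation))
  ref <- mats$expression
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!all(dim(m) == dim(ref))) stopf("%s has mismatched dimensions", nm)
    if (!is.null(rownames(ref)) && !identical(rownames(m), rownames(ref))) {
      stopf("%s sample ordering differs from expression", nm)
    }
    if (!is.null(colnames(ref)) && !identical(colnames(m), colnames(ref))) {
      stopf("%s gene ordering differs from expression", nm)
    }
  }
  me <- mats$methylation
  if (any(!is.na(me) & (me < 0 | me > 1))) {
    stopf("methylation beta values must lie in [0, 1]")
  }
  if (is.null(rownames(ref))) {
    rn <- sprintf("S%04d", seq_len(nrow(ref)))
    mats <- lapply(mats, function(m) { rownames(m) <- rn; m })
  }
  if (is.null(colnames(ref))) {
    cn <- sprintf("G%04d", seq_len(ncol(ref)))
    mats <- lapply(mats, function(m) { colnames(m) <- cn; m })
  }
  structure(c(mats,
              list(sample_ids = rownames(mats$expression),
                   gene_ids = colnames(mats$expression))),
            class = "MolecularProfiles")
}

#' @export
print.MolecularProfiles <- function(x, ...) {
  cat(sprintf("MolecularProfiles: %d samples x %d genes (expression, copy number, methylation)\n",
              length(x$sample_ids), length(x$gene_ids)))
  invisible(x)
}

# Validate a gene annotation table (0-based half-open coordinates).
as_gene_table <- function(genes) {
  if (!is.data.frame(genes)) stopf("gene annotations must be a data.frame")
  needed <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(needed, names(genes))
  if (length(miss)) stopf("gene table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(genes$strand)) genes$strand <- "*"
  genes$chrom <- as.character(genes$chrom)
  bad <- which(!(genes$start < genes$end))
  if (length(bad)) stopf("gene record %d (%s): start >= end",
                         bad[1], genes$gene_id[bad[1]])
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate gene_id: %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  genes[c("gene_id", "chrom", "start", "end", "strand")]
}

# Validate a GWAS summary table; rows with p outside (0, 1] are dropped
# with a warning, and rows are returned sorted by (chrom, pos).
as_gwas_table <- function(gwas) {
  needed <- c("snp_id", "chrom", "pos", "maf", "p")
  miss <- setdiff(needed, names(gwas))
  if (length(miss)) stopf("GWAS summary lacks column(s): %s",
                          paste(miss, collapse = ", "))
  gwas$chrom <- as.character(gwas$chrom)
  bad <- !(gwas$p > 0 & gwas$p <= 1) | is.na(gwas$p)
  if (any(bad)) {
    warnf("dropping %d GWAS row(s) with p outside (0, 1]", sum(bad))
    gwas <- gwas[!bad, , drop = FALSE]
  }
  gwas <- gwas[order(gwas$chrom, gwas$pos), , drop = FALSE]
  rownames(gwas) <- NULL
  gwas
}

# Validate a differential-expression table.
as_de_table <- function(de) {
  needed <- c("gene_id", "fold_change", "fdr")
  miss <- setdiff(needed, names(de))
  if (length(miss)) stopf("DE table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(de$fold_change == 0, na.rm = TRUE)) {
    stopf("fold_change must be non-zero (signed linear fold change)")
  }
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE)) stopf("fdr must lie in [0, 1]")
  de
}

#' Construct a named gene set
#'
#' @param gene_ids Character vector of member gene ids.
#' @param name Label for the set.
#' @return Object of class `GeneSet`.
#' @export
gene_set <- function(gene_ids, name = "gene_set") {
  structure(list(name = name, gene_ids = unique(as.character(gene_ids))),
            class = "GeneSet")
}

# Accept either a GeneSet or a plain character vector of gene ids.
as_gene_ids <- function(x) {
  if (inherits(x, "GeneSet")) x$gene_ids else unique(as.character(x))
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}
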