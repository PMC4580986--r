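# Readers and writers for the standard formats the pipeline touches.
# All writers emit UTF-8, tab-delimited text with '.' for missing values;
# all readers re-read their own writers' output to an equal value.

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    na.strings = c("NA", "."), stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "."
  out
}

#' Read genotypes from a VCF or dosage TSV file
#'
#' For VCF input, GT fields are converted to alt-allele dosage counts and the
#' DS (imputed dosage) field is used instead when present.  Multi-allelic
#' records are skipped with a warning.  The folded allele frequency is taken
#' from an INFO `MAF=` key when present, otherwise computed from the data.
#' The dosage TSV dialect has samples as rows, SNPs as columns and the first
#' column `sample_id`; it carries no coordinates, so `chrom`/`pos` are `NA`.
#'
#' @param path File path.  Format is inferred from the extension
#'   (`.vcf` vs anything else) unless `format` is given.
#' @param format One of "auto", "vcf", "dosage".
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "dosage"
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stopf("failed to parse VCF %s: %s",
                                            path, conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stopf("VCF %s contains no records", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warnf("skipping %d multi-allelic VCF record(s)", sum(multi))
    vcf@fix <- vcf@fix[!multi, , drop = FALSE]
    vcf@gt <- vcf@gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  if (anyDuplicated(ids)) stopf("duplicate snp_id in VCF: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- t(gt_to_dosage(gt))
  }
  info <- vcfR::getINFO(vcf)
  maf <- suppressWarnings(as.numeric(sub(".*MAF=([0-9.eE+-]+).*", "\\1", info)))
  maf[!grepl("MAF=", info)] <- NA_real_
  af <- colMeans(dos, na.rm = TRUE) / 2
  emp <- pmin(af, 1 - af)
  maf[is.na(maf)] <- emp[is.na(maf)]
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref_allele = fix$REF, alt_allele = fix$ALT,
                     maf = maf, stringsAsFactors = FALSE)
  colnames(dos) <- ids
  genotype_matrix(dos, snps)
}

# Convert a matrix of diploid GT strings ("0/1", "1|1", "./.") to dosages.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  val <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }, numeric(1))
  out <- matrix(val[match(gt, u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

read_genotypes_dosage <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample_id") {
    stopf("dosage TSV %s must have first column 'sample_id'", path)
  }
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$sample_id
  ids <- colnames(dos)
  af <- colMeans(dos, na.rm = TRUE) / 2
  snps <- data.frame(snp_id = ids, chrom = NA_character_, pos = NA_integer_,
                     ref_allele = NA_character_, alt_allele = NA_character_,
                     maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  genotype_matrix(dos, snps)
}

#' Write genotypes to VCF or dosage TSV
#'
#' The VCF writer emits GT (rounded hard call) and DS (exact dosage) per
#' sample plus an INFO `MAF=` key, so a write/read round trip reproduces the
#' object exactly.  Writing VCF requires coordinates; objects read from a
#' dosage TSV can only be written back as dosage TSV.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path; extension `.vcf` selects VCF.
#' @param format One of "auto", "vcf", "dosage".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "dosage"
  }
  if (format == "dosage") {
    df <- data.frame(sample_id = gm$sample_ids, gm$dosages,
                     check.names = FALSE, stringsAsFactors = FALSE)
    return(write_tsv(df, path))
  }
  if (anyNA(gm$snps$pos) || anyNA(gm$snps$chrom)) {
    stopf("cannot write VCF: SNP coordinates are missing (use format='dosage')")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Folded allele frequency\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gm$dosages))) {
    ds <- gm$dosages[, j]
    hard <- round(ds)
    gt <- ifelse(is.na(ds), "./.", gt_codes[hard + 1])
    field <- paste0(gt, ":", fmt_num(ds))
    s <- gm$snps[j, ]
    writeLines(paste(c(s$chrom, s$pos, s$snp_id,
                       s$ref_allele %||% "A", s$alt_allele %||% "G",
                       ".", ".", paste0("MAF=", fmt_num(s$maf)), "GT:DS",
                       field), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene annotations from a BED file
#'
#' BED coordinates (0-based half-open) are kept unchanged as the internal
#' convention.  Column 4 is the gene id and must be unique; column 6, when
#' present, is the strand (ignored by all downstream windows, which are
#' strand-symmetric).
#'
#' @param path BED4+ file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(as_gene_table(data.frame(gene_id = character(), chrom = character(),
                                    start = integer(), end = integer(),
                                    strand = character())))
  }
  parts <- strsplit(lines, "\t| +")
  ncols <- lengths(parts)
  if (any(ncols < 4)) stopf("BED record %d has fewer than 4 columns",
                            which(ncols < 4)[1])
  get <- function(i) vapply(parts, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    stopf("BED record %d has non-numeric coordinates",
          which(is.na(start) | is.na(end))[1])
  }
  strand <- if (all(ncols >= 6)) get(6) else rep("*", length(parts))
  as_gene_table(data.frame(gene_id = get(4), chrom = get(1),
                           start = start, end = end, strand = strand,
                           stringsAsFactors = FALSE))
}

#' Write gene annotations as BED
#' @param genes Gene table as returned by [read_gene_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(genes, path) {
  genes <- as_gene_table(genes)
  lines <- paste(genes$chrom, genes$start, genes$end, genes$gene_id,
                 0, genes$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read matched molecular profile matrices
#'
#' Each file is a samples x genes TSV whose first column is `sample_id`.
#'
#' @param expression,copy_number,methylation Paths to the three matrices.
#' @return A [molecular_profiles()] object.
#' @export
read_profiles <- function(expression, copy_number, methylation) {
  read_mat <- function(path) {
    df <- read_tsv(path)
    if (names(df)[1] != "sample_id") {
      stopf("profile TSV %s must have first column 'sample_id'", path)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    m
  }
  molecular_profiles(read_mat(expression), read_mat(copy_number),
                     read_mat(methylation))
}

#' Write molecular profiles to three TSV files
#' @param profiles A [molecular_profiles()] object.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(expression = file.path(dir, "expression.tsv"),
           copy_number = file.path(dir, "copy_number.tsv"),
           methylation = file.path(dir, "methylation.tsv"))
  for (nm in names(out)) {
    df <- data.frame(sample_id = profiles$sample_ids, profiles[[nm]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, out[[nm]])
  }
  invisible(out)
}

#' Read GWAS summary statistics
#'
#' Requires header columns `snp_id`, `chrom`, `pos` (1-based), `maf`, `p`.
#' Rows with p outside (0, 1] are rejected with a warning; rows are returned
#' sorted by (chrom, pos).
#'
#' @param path TSV file.
#' @return `data.frame` of GWAS SNPs.
#' @export
read_gwas_summary <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as_gwas_table(read_tsv(path))
}

#' Write GWAS summary statistics
#' @param gwas GWAS table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  write_tsv(as_gwas_table(gwas), path)
}

#' Read a differential-expression table
#'
#' Requires columns `gene_id`, `fold_change` (signed linear fold change,
#' negative = down-regulated) and `fdr`.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as_de_table(read_tsv(path))
}

#' Write a differential-expression table
#' @param de DE table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write_tsv(as_de_table(de), path)
}
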