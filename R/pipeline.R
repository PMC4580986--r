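# End-to-end orchestration: simulate -> adjust -> eqtl -> enrich, with a
# single global seed, per-stage outputs, and a manifest of input hashes so
# reruns are verifiably reproducible.

#' Build and validate a pipeline configuration
#'
#' Either `sim` is given (a [sim_config()]; all inputs are generated) or
#' every required input path must exist.  Validation happens here, before
#' any compute, so misconfigured runs fail fast.
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param seed Global seed; every stage derives its substream from it.
#' @param sim Optional [sim_config()]; its seed is overridden by `seed`.
#' @param genotypes,genes,expression,copy_number,methylation,gwas,de Input
#'   paths, required when `sim` is `NULL` (gwas/de only when the matching
#'   stage is enabled).
#' @param loci Index SNP ids for the scan; `NULL` with `sim` means
#'   "all planted eQTL SNPs".
#' @param window,r2_threshold,fdr_call_threshold Scan parameters.
#' @param flanks,thresholds,n_perm Enrichment parameters.
#' @param run_eqtl,run_enrichment Stage switches.
#' @param n_gwas_snps GWAS panel size when simulating.
#' @return Object of class `RunConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            genotypes = NULL, genes = NULL,
                            expression = NULL, copy_number = NULL,
                            methylation = NULL, gwas = NULL, de = NULL,
                            loci = NULL, window = 250000,
                            r2_threshold = 0.7, fdr_call_threshold = 0.1,
                            flanks = c(10000, 25000, 50000, 100000),
                            thresholds = c(1e-3, 1e-4, 1e-5),
                            n_perm = 10000,
                            run_eqtl = TRUE, run_enrichment = TRUE,
                            n_gwas_snps = 20000L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              paths = list(genotypes = genotypes, genes = genes,
                           expression = expression, copy_number = copy_number,
                           methylation = methylation, gwas = gwas, de = de),
              loci = loci, window = window, r2_threshold = r2_threshold,
              fdr_call_threshold = fdr_call_threshold, flanks = flanks,
              thresholds = thresholds, n_perm = n_perm,
              run_eqtl = run_eqtl, run_enrichment = run_enrichment,
              n_gwas_snps = as.integer(n_gwas_snps))
  validate_run_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$sim)) {
    need <- c("genotypes", "genes", "expression", "copy_number", "methylation")
    if (cfg$run_enrichment) need <- c(need, "gwas", "de")
    for (nm in need) {
      p <- cfg$paths[[nm]]
      if (is.null(p)) stopf("validation error: input '%s' is required", nm)
      if (!file.exists(p)) stopf("validation error: input '%s' not found: %s",
                                 nm, p)
    }
    if (cfg$run_eqtl && is.null(cfg$loci)) {
      stopf("validation error: 'loci' required when not simulating")
    }
  } else if (!inherits(cfg$sim, "SimConfig")) {
    stopf("validation error: `sim` must be a sim_config()")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a `sim:` mapping is
#' passed to [sim_config()].
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read (e.g. `seed`).
#' @return A validated `RunConfig`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Executes simulate (optional), adjust + variance decomposition, the
#' cis-eQTL scan and the enrichment battery, writing per-stage TSV/JSON
#' outputs plus `manifest.json` (parameters, seed, package version and the
#' MD5 of every output) and a human-readable `summary.txt` under
#' `config$out_dir`.  Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config A [pipeline_config()] result.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  # --- stage: inputs -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    message("stage simulate: generating input bundle")
    in_dir <- file.path(config$out_dir, "inputs")
    bundle <- simulate_bundle(sim, n_gwas_snps = config$n_gwas_snps,
                              out_dir = in_dir)
    outputs <- c(outputs, list.files(in_dir, full.names = TRUE))
    genotypes <- bundle$genotypes
    genes <- bundle$genes
    profiles <- bundle$profiles
    gwas <- bundle$gwas
    de <- bundle$de
    truth <- bundle$truth
    loci <- config$loci %||% unique(truth$eqtls$snp_id)
  } else {
    message("stage load: reading inputs")
    genotypes <- read_genotypes(config$paths$genotypes)
    genes <- read_gene_annotations(config$paths$genes)
    profiles <- read_profiles(config$paths$expression,
                              config$paths$copy_number,
                              config$paths$methylation)
    gwas <- if (config$run_enrichment) read_gwas_summary(config$paths$gwas)
    de <- if (config$run_enrichment) read_de_table(config$paths$de)
    loci <- config$loci
  }

  # --- stage: adjust -------------------------------------------------------
  message("stage adjust: regressing out copy number and methylation")
  adjusted <- adjust_expression(profiles)
  emit(data.frame(sample_id = adjusted$sample_ids, adjusted$residuals,
                  check.names = FALSE),
       "residuals.tsv", write_tsv)
  emit(adjusted$fits, "adjustment_fits.tsv", write_tsv)

  # --- stage: eqtl ---------------------------------------------------------
  scan <- NULL
  if (config$run_eqtl) {
    message("stage eqtl: scanning cis windows around ", length(loci), " loci")
    scan <- run_scan(adjusted, genotypes, genes, loci,
                     r2_threshold = config$r2_threshold,
                     window = config$window,
                     fdr_call_threshold = config$fdr_call_threshold)
    emit(as.data.frame(scan), "eqtl_results.tsv", write_tsv)
  }

  # variance decomposition: planted pairs when simulating, else the
  # significant scan pairs
  pairs <- if (!is.null(truth)) {
    truth$eqtls[c("snp_id", "gene_id")]
  } else if (!is.null(scan)) {
    scan[scan$significant, c("snp_id", "gene_id")]
  }
  decomp <- variance_decomposition(profiles, genotypes, pairs)
  emit(list(frac_cn = decomp$frac_cn, frac_meth = decomp$frac_meth,
            frac_eqtl = decomp$frac_eqtl, n_genes_used = decomp$n_genes_used),
       "variance_decomposition.json",
       function(obj, path) jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                                digits = NA))

  # --- stage: enrich -------------------------------------------------------
  suite <- NULL
  targets <- NULL
  if (config$run_enrichment) {
    message("stage enrich: K-S / Fisher / GSEA battery")
    targets <- select_targets(de)
    suite <- enrichment_suite(gwas, genes, targets,
                              flanks = config$flanks,
                              thresholds = config$thresholds,
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 9))
    emit(enrichment_table(suite), "enrichment_table.tsv", write_tsv)
    emit(list(gsea = suite$gsea[c("es", "p", "n_perm", "n_hits", "flank")],
              n_targets = length(targets$gene_ids)),
         "enrichment_gsea.json",
         function(obj, path) jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                                  digits = NA))
  }

  # --- manifest and summary ------------------------------------------------
  manifest <- list(
    package = "eqtlenrich",
    version = as.character(utils::packageVersion("eqtlenrich")),
    seed = config$seed,
    parameters = config[c("window", "r2_threshold", "fdr_call_threshold",
                          "flanks", "thresholds", "n_perm")],
    files = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    sprintf("eqtlenrich run (seed %d)", config$seed),
    sprintf("samples: %d, genes: %d", length(profiles$sample_ids),
            length(profiles$gene_ids)),
    sprintf("variance explained: CN %.3f%%, methylation %.3f%%, cis genotype %.4f%%",
            100 * decomp$frac_cn, 100 * decomp$frac_meth,
            100 * decomp$frac_eqtl),
    if (!is.null(scan)) {
      sprintf("eqtl scan: %d pairs tested, %d significant at FDR <= %g",
              nrow(scan), sum(scan$significant), config$fdr_call_threshold)
    },
    if (!is.null(suite)) {
      c(sprintf("enrichment targets: %d genes", length(targets$gene_ids)),
        sprintf("GSEA: ES %.3f, p %.4g", suite$gsea$es, suite$gsea$p))
    })
  writeLines(unlist(summary_lines), file.path(config$out_dir, "summary.txt"))
  invisible(list(adjusted = adjusted, scan = scan, decomposition = decomp,
                 enrichment = suite, truth = truth, manifest = manifest))
}
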