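## cli_reporting: end-to-end orchestration, the GTA report and the run
## manifest. Config is a flat JSON object; CLI flags (inst/cli.R)
## override config keys.

PIPELINE_DEFAULTS <- list(
  maf_min = 0.05, miss_max = 0.20, spacing_bp = 50000,
  Q = 2, K = 2, alpha = 1e-4, min_class_count = 5, seed = 1)

## merge user config over defaults; required keys checked by run_pipeline
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  utils::modifyList(PIPELINE_DEFAULTS, config)
}

#' Join significant gene-trait associations with their key variants
#'
#' One row per significant gene x trait, joined with the flagged key
#' natural variant from the SNP scan, sorted by (chromosome, gene
#' start, trait); written via [write_results()] (header-only when
#' nothing is significant).
#'
#' @param gene_results output of [run_gwha_scan()].
#' @param snp_results output of [run_snp_scan()] after
#'   [key_variants_all()].
#' @param path output TSV path.
#' @return the joined `data.frame`, invisibly.
#' @export
report_gta_table <- function(gene_results, snp_results, path) {
  sig <- gene_results[which(gene_results$significant), , drop = FALSE]
  out <- data.frame(
    gene_id = sig$gene_id, trait = sig$trait, chrom = sig$chrom,
    n_haplotypes_tested = sig$n_classes_tested,
    n_accessions_used = sig$n_used, F = sig$F, df1 = sig$df1,
    df2 = sig$df2, p_value = sig$p_value, significant = sig$significant,
    key_snp_id = rep(NA_character_, nrow(sig)),
    key_snp_pos = rep(NA_integer_, nrow(sig)),
    key_snp_p = rep(NA_real_, nrow(sig)),
    key_snp_alleles = rep(NA_character_, nrow(sig)),
    stringsAsFactors = FALSE)
  if (nrow(out) > 0 && nrow(snp_results) > 0) {
    key <- snp_results[which(snp_results$is_key_variant), , drop = FALSE]
    m <- match(paste(out$gene_id, out$trait),
               paste(key$gene_id, key$trait))
    hit <- !is.na(m)
    out$key_snp_id[hit] <- key$snp_id[m[hit]]
    out$key_snp_pos[hit] <- key$pos[m[hit]]
    out$key_snp_p[hit] <- key$p_value[m[hit]]
    out$key_snp_alleles[hit] <- paste0(key$ref[m[hit]], "/", key$alt[m[hit]])
  }
  write_results(out, path)
  invisible(out)
}

#' Run the full pipeline
#'
#' Stages run in fixed order: read inputs, SNP QC filter, gene SNP
#' index, haplotype construction (+ rare-class exclusion), thinning +
#' PCA + clustering + kinship, gene-level haplotype scan, single-SNP
#' scan of the significant genes, reports. A JSON manifest with per-
#' stage record counts, input checksums and output checksums is written
#' last. Any stage failure aborts with the stage name (a partial
#' manifest is written).
#'
#' @param config a path to a JSON config or a named list. Required
#'   keys: `vcf`, `gff`, `traits`, `out_dir`. Optional (defaults):
#'   `maf_min` (0.05), `miss_max` (0.20), `spacing_bp` (50000), `Q` (2),
#'   `K` (2), `alpha` (1e-4), `min_class_count` (5), `seed` (1).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  for (k in c("vcf", "gff", "traits", "out_dir"))
    if (is.null(cfg[[k]])) stop("config error: missing key '", k, "'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "gwhap", version = as.character(
    utils::packageVersion("gwhap")), config = cfg, seed = cfg$seed,
    inputs = list(), stages = list())
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[gwhap] stage %-12s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  add_counts <- function(name, counts) {
    manifest$stages[[name]] <<- counts
  }

  inputs <- stage("read", {
    list(panel = read_vcf(cfg$vcf), genes = read_gff3(cfg$gff),
         traits = read_trait_table(cfg$traits))
  })
  manifest$inputs <- as.list(tools::md5sum(c(vcf = cfg$vcf, gff = cfg$gff,
                                             traits = cfg$traits)))
  add_counts("read", list(
    accessions = length(inputs$panel$accession_ids),
    snps_in = length(inputs$panel$snp_ids),
    genes_annotated = nrow(inputs$genes),
    trait_accessions = nrow(inputs$traits),
    traits = length(trait_names(inputs$traits))))

  panel <- stage("filter", {
    qc <- compute_snp_qc(inputs$panel, cfg$maf_min, cfg$miss_max)
    filter_panel(inputs$panel, qc)
  })
  add_counts("filter", list(snps_in = length(inputs$panel$snp_ids),
                            snps_out = length(panel$snp_ids)))

  idx <- stage("gene_index", assign_snps_to_genes(panel, inputs$genes))
  add_counts("gene_index", list(snps_in = length(panel$snp_ids),
                                genes_with_snps = length(idx)))

  haps <- stage("haplotypes",
                build_all_haplotypes(panel, idx, cfg$min_class_count))
  add_counts("haplotypes", list(
    genes = length(haps),
    genes_testable = sum(!vapply(haps, `[[`, logical(1), "untestable")),
    accessions_excluded_total = sum(vapply(haps, `[[`, integer(1),
                                           "n_excluded"))))

  struct <- stage("structure", {
    thin <- thin_snps(panel, cfg$spacing_bp)
    dm <- dosage_matrix(panel, thin)
    s <- pca_structure(dm, n_components = max(cfg$Q, 3))
    s$cluster_labels <- cluster_accessions(s, K = cfg$K, seed = cfg$seed)
    attr(s, "kinship") <- centered_ibs_kinship(dm)
    attr(s, "n_thinned") <- length(thin)
    s
  })
  add_counts("structure", list(snps_thinned = attr(struct, "n_thinned"),
                               pcs = ncol(struct$pc_coords), K = cfg$K))

  sc <- scan_config(alpha = cfg$alpha, Q = cfg$Q,
                    min_class_count = cfg$min_class_count, seed = cfg$seed)
  gene_res <- stage("gwha", run_gwha_scan(panel, idx, haps, inputs$traits,
                                          struct, sc, genes = inputs$genes))
  add_counts("gwha", list(tests_run = nrow(gene_res),
                          significant = sum(gene_res$significant,
                                            na.rm = TRUE)))

  snp_res <- stage("snpscan", {
    sig <- gene_res[which(gene_res$significant), c("gene_id", "trait")]
    r <- run_snp_scan(panel, idx, inputs$traits, struct, sc, pairs = sig)
    key_variants_all(r)
  })
  add_counts("snpscan", list(snp_tests = sum(!snp_res$skipped),
                             snp_skipped = sum(snp_res$skipped),
                             key_variants = sum(snp_res$is_key_variant)))

  outs <- stage("report", {
    o <- c(gene_results = file.path(cfg$out_dir, "gene_results.tsv"),
           snp_results = file.path(cfg$out_dir, "snp_results.tsv"),
           gta = file.path(cfg$out_dir, "gta_table.tsv"),
           pcs = file.path(cfg$out_dir, "pcs.tsv"),
           kinship = file.path(cfg$out_dir, "kinship.tsv"),
           hap_summary = file.path(cfg$out_dir, "haplotype_summary.tsv"))
    gr_out <- gene_res
    gr_out$F <- format(gr_out$F, digits = 17, trim = TRUE)
    gr_out$p_value <- format(gr_out$p_value, digits = 17, trim = TRUE)
    utils::write.table(gr_out, o["gene_results"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sr_out <- snp_res
    sr_out$beta <- format(sr_out$beta, digits = 17, trim = TRUE)
    sr_out$p_value <- format(sr_out$p_value, digits = 17, trim = TRUE)
    utils::write.table(sr_out, o["snp_results"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report_gta_table(gene_res, snp_res, o["gta"])
    write_structure(struct, o["pcs"])
    kin <- attr(struct, "kinship")
    utils::write.table(data.frame(accession_id = rownames(kin), kin,
                                  check.names = FALSE),
                       o["kinship"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    hs <- summarize_haplotypes(haps)
    utils::write.table(
      data.frame(n_haplotypes = names(hs$histogram),
                 n_genes = hs$histogram),
      o["hap_summary"], sep = "\t", quote = FALSE, row.names = FALSE)
    mq <- export_manhattan_qq(gene_res, file.path(cfg$out_dir, "gwha"))
    c(o, manhattan = mq[1], qq = mq[2])
  })
  manifest$outputs <- as.list(tools::md5sum(unname(outs)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
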