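## haplotype_core: per-gene haplotype classes from gene-body SNP calls.

#' Build haplotype classes for one gene
#'
#' Every accession's gene-body calls are turned into an allele string
#' (hom-ref -> reference base, hom-alt -> alternate base). An accession
#' with a heterozygous or missing call at *any* gene SNP is excluded for
#' this gene: the panels targeted are inbred, so residual heterozygosity
#' is treated as noise rather than a third allele, and missing calls are
#' not imputed to avoid fabricating classes. Identical strings share a
#' class; classes are labelled `Hap1`, `Hap2`, ... in descending
#' accession count (ties broken by first occurrence).
#'
#' @param panel a [genotype_panel()].
#' @param gene_snp_index index from [assign_snps_to_genes()].
#' @param gene_id gene to build.
#' @return an object of class `haplotype_table`: list with `gene_id`,
#'   `chrom`, `snp_idx`, `snp_ids`, `class_defs` (allele strings),
#'   `class_counts` (named by `Hap*` labels), `assignment` (named integer
#'   class index per accession, `NA` = excluded), `n_excluded`,
#'   `untestable`.
#' @export
build_gene_haplotypes <- function(panel, gene_snp_index, gene_id) {
  if (!gene_id %in% names(gene_snp_index))
    stop("gene not in index: ", gene_id)
  snp_idx <- gene_snp_index[[gene_id]]
  calls <- panel$calls[, snp_idx, drop = FALSE]
  excluded <- rowSums(is.na(calls) | calls == CALL_HET) > 0
  ref <- panel$ref[snp_idx]
  alt <- panel$alt[snp_idx]
  n <- nrow(calls)
  strings <- rep(NA_character_, n)
  if (any(!excluded)) {
    sub <- calls[!excluded, , drop = FALSE]
    ch <- matrix(rep(ref, each = nrow(sub)), nrow = nrow(sub))
    ch[sub == CALL_ALT_HOM] <- matrix(rep(alt, each = nrow(sub)),
                                      nrow = nrow(sub))[sub == CALL_ALT_HOM]
    strings[!excluded] <- apply(ch, 1, paste, collapse = "")
  }
  ## classes in descending count, ties by first occurrence
  obs <- strings[!is.na(strings)]
  defs <- unique(obs)
  counts <- as.integer(table(factor(obs, levels = defs)))
  ord <- order(-counts, seq_along(defs))
  defs <- defs[ord]
  counts <- counts[ord]
  assignment <- match(strings, defs)
  names(assignment) <- panel$accession_ids
  names(counts) <- paste0("Hap", seq_along(defs))
  structure(
    list(gene_id = gene_id,
         chrom = if (length(snp_idx)) panel$chrom[snp_idx[1]] else NA_character_,
         snp_idx = snp_idx, snp_ids = panel$snp_ids[snp_idx],
         class_defs = defs, class_counts = counts,
         assignment = assignment, n_excluded = sum(excluded),
         n_collapsed = 0L, untestable = length(defs) < 2),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table %s: %d SNP(s), %d class(es), %d excluded%s\n",
              x$gene_id, length(x$snp_idx), length(x$class_defs),
              x$n_excluded, if (x$untestable) " [untestable]" else ""))
  invisible(x)
}

#' Exclude rare haplotype classes
#'
#' Classes carried by fewer than `min_count` accessions are removed and
#' their members excluded (not pooled into a pseudo-class: a pooled
#' "other" class has no biological identity and distorts the class
#' F-test). Remaining classes are re-ordered and re-labelled; if fewer
#' than two remain the gene is flagged untestable.
#'
#' @param table a `haplotype_table`.
#' @param min_count minimum accessions per retained class (default 5).
#' @return a `haplotype_table` with rare classes removed; `n_collapsed`
#'   records how many accessions were newly excluded.
#' @export
collapse_rare_haplotypes <- function(table, min_count = 5) {
  keep <- which(table$class_counts >= min_count)
  dropped <- setdiff(seq_along(table$class_counts), keep)
  dropped_members <- sum(table$class_counts[dropped])
  if (length(dropped) == 0) return(table)
  new_defs <- table$class_defs[keep]
  new_counts <- table$class_counts[keep]
  remap <- rep(NA_integer_, length(table$class_defs))
  remap[keep] <- seq_along(keep)
  assignment <- remap[table$assignment]
  names(assignment) <- names(table$assignment)
  names(new_counts) <- paste0("Hap", seq_along(keep), recycle0 = TRUE)
  table$class_defs <- new_defs
  table$class_counts <- new_counts
  table$assignment <- assignment
  table$n_collapsed <- as.integer(dropped_members)
  table$n_excluded <- table$n_excluded + as.integer(dropped_members)
  table$untestable <- length(new_defs) < 2
  table
}

#' Summarize haplotype counts across genes
#'
#' Histogram of the number of haplotype classes per gene (before any
#' rare-class exclusion), the gene-level summary behind
#' haplotype-diversity figures.
#'
#' @param tables list of `haplotype_table` objects.
#' @return list with `h_g` (named integer, classes per gene) and
#'   `histogram` (named integer, genes per class count).
#' @export
summarize_haplotypes <- function(tables) {
  if (length(tables) == 0) stop("no haplotype tables given")
  h <- vapply(tables, function(t) length(t$class_defs), integer(1))
  names(h) <- vapply(tables, `[[`, character(1), "gene_id")
  tab <- table(h)
  list(h_g = h,
       histogram = stats::setNames(as.integer(tab), names(tab)))
}

#' Build (and optionally rare-collapse) haplotypes for all genes
#'
#' @param panel a [genotype_panel()].
#' @param gene_snp_index index from [assign_snps_to_genes()].
#' @param min_count rare-class threshold passed to
#'   [collapse_rare_haplotypes()]; `NULL` skips collapsing.
#' @return named list of `haplotype_table` objects.
#' @export
build_all_haplotypes <- function(panel, gene_snp_index, min_count = 5) {
  tabs <- lapply(names(gene_snp_index), function(g)
    build_gene_haplotypes(panel, gene_snp_index, g))
  names(tabs) <- names(gene_snp_index)
  if (!is.null(min_count))
    tabs <- lapply(tabs, collapse_rare_haplotypes, min_count = min_count)
  tabs
}

#' Export haplotype assignments as a long TSV
#'
#' One row per assigned accession: `gene_id`, `accession_id`, `haplotype`
#' label and the allele string.
#'
#' @param tables list of `haplotype_table` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_assignments <- function(tables, path) {
  rows <- lapply(tables, function(t) {
    a <- t$assignment[!is.na(t$assignment)]
    if (length(a) == 0) return(NULL)
    data.frame(gene_id = t$gene_id, accession_id = names(a),
               haplotype = paste0("Hap", a),
               alleles = t$class_defs[a], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), accession_id = character(),
                      haplotype = character(), alleles = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
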