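## io_formats: every external representation in and out of the domain types.
## VCF parsing is delegated to VariantAnnotation, GFF3 to rtracklayer;
## trait tables and result tables are plain CSV/TSV.

#' Read a VCF of biallelic SNPs into a genotype panel
#'
#' Diploid GT fields are mapped to call codes: `0/0` -> 0 (hom ref),
#' `1/1` -> 2 (hom alt), `0/1` or `1/0` -> 1 (het), `./.` -> `NA`.
#' Phased separators (`|`) are treated like unphased (`/`): the panels
#' this package targets are inbred and essentially homozygous, so phase
#' carries no information. Multiallelic records and indels are skipped
#' with a single warning reporting the count.
#'
#' @param path path to an uncompressed or bgzipped VCF 4.x file.
#' @param region_filter optional `data.frame` with columns `chrom`,
#'   `start`, `end`; only SNPs inside one of the intervals are kept.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path, region_filter = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  keep <- n_alt == 1 & !is.na(alt1) &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0)
    warning(n_skip, " multiallelic/non-SNP record(s) skipped in ", path)
  if (!any(keep))
    stop("no biallelic SNPs parsed from ", path,
         " (", length(keep), " records, ", n_skip, " skipped)")
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0"] <- CALL_REF_HOM
  code[gt == "1/1"] <- CALL_ALT_HOM
  code[gt == "0/1" | gt == "1/0"] <- CALL_HET
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  ids <- rownames(gt)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0(chrom, "_", pos)
  panel <- genotype_panel(colnames(gt), ids, chrom, pos,
                          ref[keep], alt1[keep], t(code))
  if (!is.null(region_filter)) {
    sel <- rep(FALSE, length(panel$pos))
    for (i in seq_len(nrow(region_filter))) {
      sel <- sel | (panel$chrom == region_filter$chrom[i] &
                      panel$pos >= region_filter$start[i] &
                      panel$pos <= region_filter$end[i])
    }
    panel <- subset_snps(panel, which(sel))
  }
  panel
}

#' Write a genotype panel as VCF
#'
#' Emits a minimal VCF 4.2 with a GT FORMAT field; the inverse of
#' [read_vcf()] (round-trips calls, positions and alleles exactly).
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gwhap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", panel$accession_ids), collapse = "\t")),
    con)
  gt_map <- c("0/0", "0/1", "1/1")
  m <- length(panel$snp_ids)
  if (m > 0) {
    gt <- matrix(gt_map[panel$calls + 1L], nrow = nrow(panel$calls))
    gt[is.na(gt)] <- "./."
    lines <- paste(panel$chrom, panel$pos, panel$snp_ids, panel$ref,
                   panel$alt, ".", "PASS", ".", "GT",
                   apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param feature_type feature type to extract (column 3), default `"gene"`.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 ", path,
                                          ": ", conditionMessage(e)))
  gr <- gr[gr$type == feature_type]
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  ids <- gr$ID
  if (is.null(ids)) stop("GFF3 features lack ID attributes: ", path)
  df <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(df$gene_id)) stop("duplicate gene IDs in ", path)
  df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
}

#' Write gene models as GFF3
#'
#' @param genes a `data.frame` as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$source <- "gwhap"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a trait table from CSV
#'
#' Expected layout: header row, accession identifier in the first column,
#' one numeric column per trait. Empty cells become `NA` (the accession is
#' retained). Values are stored in % (g/100 g); pass `units = "g_per_kg"`
#' to convert tables recorded in g/kg (divided by 10 on read).
#'
#' @param path CSV path.
#' @param units `"percent"` (default) or `"g_per_kg"`.
#' @return a `data.frame` of class `trait_table`: column `accession_id`
#'   plus one numeric column per trait.
#' @export
read_trait_table <- function(path, units = c("percent", "g_per_kg")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("trait table needs an accession column plus traits")
  names(df)[1] <- "accession_id"
  df$accession_id <- as.character(df$accession_id)
  if (anyDuplicated(df$accession_id))
    stop("duplicate accession ids in ", path)
  for (j in 2:ncol(df)) {
    df[[j]] <- suppressWarnings(as.numeric(df[[j]]))
    if (units == "g_per_kg") df[[j]] <- df[[j]] / 10
  }
  vals <- unlist(df[-1])
  if (any(vals < 0, na.rm = TRUE)) stop("negative trait values in ", path)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a trait table as CSV
#' @param traits a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Trait names of a trait table
#' @param traits a `trait_table`.
#' @return character vector of trait column names.
#' @export
trait_names <- function(traits) setdiff(names(traits), "accession_id")

#' Trait table as a numeric matrix
#'
#' @param traits a `trait_table`.
#' @return numeric matrix, accessions (rownames) x traits.
#' @export
trait_matrix <- function(traits) {
  m <- as.matrix(as.data.frame(traits)[trait_names(traits)])
  rownames(m) <- traits$accession_id
  storage.mode(m) <- "double"
  m
}

RESULT_COLUMNS <- c("gene_id", "trait", "chrom", "n_haplotypes_tested",
                    "n_accessions_used", "F", "df1", "df2", "p_value",
                    "significant", "key_snp_id", "key_snp_pos",
                    "key_snp_p", "key_snp_alleles")

#' Write association results as TSV
#'
#' Writes the canonical result columns (`gene_id`, `trait`, `chrom`,
#' `n_haplotypes_tested`, `n_accessions_used`, `F`, `df1`, `df2`,
#' `p_value`, `significant`, `key_snp_id`, `key_snp_pos`, `key_snp_p`,
#' `key_snp_alleles`). Missing columns are filled with `NA`.
#'
#' @param records a `data.frame` of per gene-by-trait records.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  for (cc in setdiff(RESULT_COLUMNS, names(records))) records[[cc]] <- NA
  out <- records[RESULT_COLUMNS]
  ## full-precision numerics so that write/read round-trips exactly
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format(out[[j]], digits = 17,
                                                 trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read association results written by [write_results()]
#' @param path TSV path.
#' @return a `data.frame` with the canonical result columns.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- c("n_haplotypes_tested", "n_accessions_used", "F", "df1", "df2",
           "p_value", "key_snp_pos", "key_snp_p")
  for (cc in intersect(num, names(df))) df[[cc]] <- as.numeric(df[[cc]])
  if ("significant" %in% names(df)) df$significant <- as.logical(df$significant)
  df
}
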