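## qc_filter: MAF/missingness filters, gene-body SNP assignment, thinning.

#' Per-SNP quality-control statistics
#'
#' Allele counting is diploid: a hom-ref call contributes two reference
#' alleles, a hom-alt call two alternate alleles, a het one of each.
#' Missing calls are excluded from the allele denominator and counted
#' toward the missing rate. A SNP passes when `maf >= maf_min` and
#' `missing_rate <= miss_max` (both boundaries inclusive, i.e. SNPs with
#' MAF *below* 0.05 or missingness *above* 20% are removed). SNPs with
#' all calls missing have undefined MAF and fail.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum missing-call fraction (default 0.20).
#' @return a `data.frame` with columns `snp_id`, `maf`, `missing_rate`,
#'   `pass`, `all_missing`.
#' @export
compute_snp_qc <- function(panel, maf_min = 0.05, miss_max = 0.20) {
  if (length(panel$snp_ids) == 0) stop("empty panel")
  calls <- panel$calls
  n <- nrow(calls)
  n_miss <- colSums(is.na(calls))
  n_called <- n - n_miss
  alt_count <- colSums(calls, na.rm = TRUE)       # calls are alt dosages
  alt_freq <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  missing_rate <- n_miss / n
  pass <- !is.na(maf) & maf >= maf_min & missing_rate <= miss_max
  data.frame(snp_id = panel$snp_ids, maf = maf,
             missing_rate = missing_rate, pass = pass,
             all_missing = n_called == 0, stringsAsFactors = FALSE)
}

#' Keep only SNPs passing quality control
#'
#' @param panel a [genotype_panel()].
#' @param qc output of [compute_snp_qc()] aligned to `panel`.
#' @return a [genotype_panel()] with exactly the passing SNPs, order
#'   preserved.
#' @export
filter_panel <- function(panel, qc) {
  stopifnot(identical(qc$snp_id, panel$snp_ids))
  keep <- which(qc$pass)
  if (length(keep) == 0)
    stop("no SNPs pass QC (", sum(!qc$pass & !is.na(qc$maf) & qc$maf == 0),
         " monomorphic, ", sum(qc$all_missing), " all-missing, ",
         length(qc$pass), " total)")
  subset_snps(panel, keep)
}

#' Assign SNPs to gene bodies
#'
#' A SNP belongs to a gene when `start <= pos <= end` (1-based, both ends
#' inclusive) on the gene's chromosome; the full annotated gene span
#' (UTRs and introns included) is used. A SNP inside two overlapping
#' genes is assigned to both. Genes without any SNP are absent from the
#' index.
#'
#' @param panel a [genotype_panel()] (typically already QC-filtered).
#' @param genes gene models as returned by [read_gff3()].
#' @return a named list, `gene_id` -> ordered integer vector of SNP
#'   indices into `panel`.
#' @export
assign_snps_to_genes <- function(panel, genes) {
  pc <- unique(panel$chrom)
  gc <- unique(genes$chrom)
  if (length(intersect(pc, gc)) == 0)
    stop("no shared chromosome labels between genotypes and annotation.\n",
         "  genotype chromosomes:  ", paste(pc, collapse = ", "), "\n",
         "  annotation chromosomes: ", paste(gc, collapse = ", "))
  snp_gr <- panel_granges(panel)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gene_gr, snp_gr, ignore.strand = TRUE)
  idx <- split(S4Vectors::subjectHits(ov),
               genes$gene_id[S4Vectors::queryHits(ov)])
  idx <- lapply(idx, function(v) sort(unique(as.integer(v))))
  ## keep gene order of the annotation
  idx[intersect(genes$gene_id, names(idx))]
}

#' Thin SNPs to an approximately even spacing
#'
#' Greedy left-to-right per chromosome: the first SNP is kept and each
#' subsequent SNP is kept when it lies at least `spacing_bp` beyond the
#' last kept SNP. Deterministic and order-preserving.
#'
#' @param panel a [genotype_panel()] sorted by (chrom, pos).
#' @param spacing_bp minimum spacing between kept SNPs (default 50 kb).
#' @return integer vector of kept SNP indices into `panel`.
#' @export
thin_snps <- function(panel, spacing_bp = 50000) {
  keep <- integer(0)
  for (cc in unique(panel$chrom)) {
    idx <- which(panel$chrom == cc)
    if (length(idx) == 0) next
    last <- -Inf
    for (i in idx) {
      if (panel$pos[i] - last >= spacing_bp || !is.finite(last)) {
        keep <- c(keep, i)
        last <- panel$pos[i]
      }
    }
  }
  keep
}
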