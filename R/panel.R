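#' @keywords internal
"_PACKAGE"

## Call coding used throughout: genotype calls are stored as the alt-allele
## dosage of an (assumed diploid, largely homozygous) accession:
##   0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
##   NA = missing.  This makes the dosage matrix a trivial cast.
CALL_REF_HOM <- 0L
CALL_HET <- 1L
CALL_ALT_HOM <- 2L

#' The 17 grain amino acids
#'
#' Trait names used by default across the package, in the conventional
#' reporting order (contents in % dry weight, g/100 g).
#' @export
aa_trait_names <- function() {
  c("Asp", "Thr", "Ser", "Glu", "Gly", "Ala", "Cys", "Val", "Met",
    "Ile", "Leu", "Tyr", "Phe", "Lys", "His", "Arg", "Pro")
}

#' Construct a genotype panel
#'
#' A `genotype_panel` holds biallelic SNP calls for a set of accessions.
#' Calls are coded as alt-allele dosage: 0 (hom ref), 1 (het), 2 (hom alt),
#' `NA` (missing). SNPs must be ordered by chromosome (grouped, in order of
#' first appearance) and strictly increasing position within a chromosome.
#'
#' @param accession_ids character vector of unique accession identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param chrom per-SNP chromosome label.
#' @param pos per-SNP 1-based coordinate (bp).
#' @param ref,alt per-SNP single-character bases in `A`,`C`,`G`,`T`.
#' @param calls integer matrix, accessions in rows, SNPs in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(accession_ids, snp_ids, chrom, pos, ref, alt, calls) {
  accession_ids <- as.character(accession_ids)
  snp_ids <- as.character(snp_ids)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  storage.mode(calls) <- "integer"
  n <- length(accession_ids)
  m <- length(snp_ids)
  stopifnot(
    !anyDuplicated(accession_ids), !anyDuplicated(snp_ids),
    length(chrom) == m, length(pos) == m,
    length(ref) == m, length(alt) == m,
    nrow(calls) == n, ncol(calls) == m
  )
  if (m > 0) {
    if (!all(ref %in% c("A", "C", "G", "T")) || !all(alt %in% c("A", "C", "G", "T")))
      stop("alleles must be single bases in A/C/G/T")
    if (anyDuplicated(paste(chrom, pos)))
      stop("duplicate (chrom, pos) in panel")
    ## chromosomes grouped in first-appearance order, pos strictly increasing
    grp <- match(chrom, unique(chrom))
    if (is.unsorted(grp))
      stop("SNPs must be grouped by chromosome")
    for (cc in unique(chrom)) {
      p <- pos[chrom == cc]
      if (length(p) > 1 && any(diff(p) <= 0))
        stop("positions must be strictly increasing within chromosome ", cc)
    }
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% 0:2))
      stop("calls must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(accession_ids, snp_ids)
  structure(
    list(accession_ids = accession_ids, snp_ids = snp_ids,
         chrom = chrom, pos = pos, ref = as.character(ref),
         alt = as.character(alt), calls = calls),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d accessions x %d SNPs on %d chromosome(s)\n",
              length(x$accession_ids), length(x$snp_ids),
              length(unique(x$chrom))))
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) {
  c(length(x$accession_ids), length(x$snp_ids))
}

#' Subset a panel by SNP index
#'
#' @param panel a `genotype_panel`.
#' @param snp_idx integer indices of SNPs to keep (in panel order).
#' @return a `genotype_panel` with the selected SNPs, order preserved.
#' @export
subset_snps <- function(panel, snp_idx) {
  snp_idx <- as.integer(snp_idx)
  genotype_panel(panel$accession_ids, panel$snp_ids[snp_idx],
                 panel$chrom[snp_idx], panel$pos[snp_idx],
                 panel$ref[snp_idx], panel$alt[snp_idx],
                 panel$calls[, snp_idx, drop = FALSE])
}

## GRanges view of the panel's SNP coordinates (width-1 loci)
panel_granges <- function(panel) {
  GenomicRanges::GRanges(panel$chrom,
                         IRanges::IRanges(panel$pos, width = 1L))
}
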