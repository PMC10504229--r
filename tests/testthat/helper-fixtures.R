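## Fixtures are built in code; nothing binary is stored.

## deterministic toy panel: 3 accessions x 4 SNPs on one chromosome
toy_panel <- function() {
  calls <- rbind(
    A1 = c(0L, 2L, 1L, 0L),
    A2 = c(2L, 0L, NA, 0L),
    A3 = c(0L, 0L, 0L, 2L))
  genotype_panel(c("A1", "A2", "A3"), paste0("s", 1:4), rep("chr1", 4),
                 c(100L, 200L, 350L, 900L),
                 c("A", "C", "G", "T"), c("G", "T", "A", "C"), calls)
}

## random panel drawn directly (independent of simulate_panel)
random_panel <- function(n = 10, m = 20, seed = 1, miss = 0.1, het = 0.05) {
  set.seed(seed)
  p_alt <- runif(m, 0.05, 0.95)
  calls <- sapply(seq_len(m), function(j) {
    g <- ifelse(runif(n) < p_alt[j], 2L, 0L)
    u <- runif(n)
    g[u < miss + het] <- 1L
    g[u < miss] <- NA_integer_
    g
  })
  if (n == 1) calls <- matrix(calls, nrow = 1)
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  chrom <- rep(c("chr1", "chr2"), length.out = 2)[rep(1:2, c(ceiling(m / 2),
                                                             floor(m / 2)))]
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ii)
    sort(sample.int(1e6, length(ii)))), use.names = FALSE)
  genotype_panel(sprintf("A%02d", seq_len(n)), sprintf("snp%03d", seq_len(m)),
                 chrom, pos, ref, alt, calls)
}

table1_path <- function() {
  system.file("extdata", "table1_top_accessions.csv", package = "gwhap")
}

table1_totals <- function() {
  utils::read.csv(system.file("extdata", "table1_totals.csv",
                              package = "gwhap"),
                  stringsAsFactors = FALSE)
}

## independent OLS oracle via explicit normal equations: returns RSS
oracle_rss <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% b)^2)
}

## minimal single-gene haplotype_table built by hand for model tests
hand_hap_table <- function(assignment, gene_id = "G1", chrom = "chr1") {
  cls <- sort(unique(assignment[!is.na(assignment)]))
  counts <- as.integer(table(factor(assignment, levels = cls)))
  structure(list(gene_id = gene_id, chrom = chrom, snp_idx = integer(0),
                 snp_ids = character(0),
                 class_defs = paste0("STR", cls),
                 class_counts = stats::setNames(counts,
                                                paste0("Hap", seq_along(cls))),
                 assignment = assignment, n_excluded = sum(is.na(assignment)),
                 n_collapsed = 0L, untestable = length(cls) < 2),
            class = "haplotype_table")
}
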