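## synthetic_data: structured inbred panels with planted haplotype
## classes and trait effects, so every pipeline stage has ground truth.

#' Simulation configuration
#'
#' Describes a diverse inbred panel of two diverged subpopulations.
#' Genes are generated from planted founder haplotypes: each gene gets
#' `H` founder allele strings over its SNPs and every accession inherits
#' one founder string (homozygous), which reproduces the limited
#' haplotype diversity of real gene bodies (a handful of classes per
#' gene) instead of the combinatorial explosion independent per-SNP
#' draws would give. With probability `divergence` a gene's founder
#' frequencies are drawn independently for the two subpopulations
#' (structure); otherwise they are shared.
#'
#' @param n_accessions panel size (default 164).
#' @param subpop_sizes sizes of the two subpopulations (default
#'   `c(40, 124)`, a minority group plus a majority group).
#' @param divergence per-gene probability of independent subpopulation
#'   founder frequencies (default 0.3).
#' @param n_genes number of genes (default 60).
#' @param n_chrom number of chromosomes genes are tiled over (default 2).
#' @param snps_per_gene inclusive integer range of SNPs per gene
#'   (default `c(1, 60)`).
#' @param haps_per_gene inclusive integer range of founder haplotypes
#'   per gene (default `c(2, 8)`, the bulk of the empirical per-gene
#'   haplotype-count distribution).
#' @param maf_spectrum range of the uniform target minor-allele
#'   frequency per SNP (default `c(0.05, 0.5)`).
#' @param missing_rate per-call missing probability (default 0.02).
#' @param het_rate per-call residual-heterozygosity probability
#'   (default 0.005).
#' @param causal_genes list of entries, each a list with `gene` (gene id
#'   or index), `trait` (name), `fve` (target fraction of trait variance
#'   explained), and either `effects` (numeric, one per planted class)
#'   or `causal_snp` (SNP index within the gene whose alt allele carries
#'   the effect).
#' @param structure_effect additive trait shift applied to the second
#'   subpopulation, in trait units (default 0).
#' @param noise_sd residual standard deviation in trait units
#'   (default 0.2).
#' @param trait_names trait columns to generate (default the 17 grain
#'   amino acids, [aa_trait_names()]).
#' @param seed integer RNG seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 164, subpop_sizes = c(40, 124),
                       divergence = 0.3, n_genes = 60, n_chrom = 2,
                       snps_per_gene = c(1, 60), haps_per_gene = c(2, 8),
                       maf_spectrum = c(0.05, 0.5), missing_rate = 0.02,
                       het_rate = 0.005, causal_genes = list(),
                       structure_effect = 0, noise_sd = 0.2,
                       trait_names = aa_trait_names(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sum(subpop_sizes) != n_accessions)
    stop("subpop_sizes must sum to n_accessions")
  stopifnot(length(subpop_sizes) == 2, divergence >= 0, divergence <= 1,
            missing_rate >= 0, missing_rate <= 1,
            het_rate >= 0, het_rate <= 1, noise_sd >= 0,
            snps_per_gene[1] >= 1, haps_per_gene[1] >= 2)
  structure(list(
    n_accessions = as.integer(n_accessions),
    subpop_sizes = as.integer(subpop_sizes),
    divergence = divergence, n_genes = as.integer(n_genes),
    n_chrom = as.integer(n_chrom),
    snps_per_gene = as.integer(snps_per_gene),
    haps_per_gene = as.integer(haps_per_gene),
    maf_spectrum = maf_spectrum, missing_rate = missing_rate,
    het_rate = het_rate, causal_genes = causal_genes,
    structure_effect = structure_effect, noise_sd = noise_sd,
    trait_names = trait_names, seed = as.integer(seed)),
    class = "sim_config")
}

## Dirichlet(1,...,1) draw of length k
.rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

## Pick a founder subset whose total frequency approximates `m`; retries
## until the subset is distinguishable from every carrier pattern already
## used within the gene (symmetric-difference founder mass >= 0.05):
## two SNPs segregating (nearly) identically are one variant pattern,
## not two distinct SNPs.
.pick_carriers <- function(qmix, m, used_patterns) {
  H <- length(qmix)
  for (attempt in seq_len(50)) {
    perm <- sample.int(H)
    cum <- cumsum(qmix[perm])
    ## carrier count whose total frequency is closest to the target
    take <- which.min(abs(cum - m))
    if (take == H) take <- H - 1
    carriers <- sort(perm[seq_len(take)])
    pat <- seq_len(H) %in% carriers
    distinct <- TRUE
    for (u in used_patterns) {
      ## a pattern and its complement segregate identically up to sign
      if (sum(qmix[xor(pat, u)]) < 0.05 ||
          sum(qmix[xor(pat, !u)]) < 0.05) { distinct <- FALSE; break }
    }
    if (distinct) return(carriers)
  }
  carriers  # near-duplicates allowed when the pattern space is exhausted
}

#' Simulate a structured inbred genotype panel
#'
#' See [sim_config()] for the generative model. Deterministic given the
#' config seed: the same config yields byte-identical panels.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [genotype_panel()]), `genes` (gene
#'   models `data.frame`), `truth` (list: `subpop` labels, per-gene
#'   planted class info, per-SNP target MAF).
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  n <- config$n_accessions
  acc <- sprintf("ACC%03d", seq_len(n))
  subpop <- stats::setNames(rep(1:2, config$subpop_sizes), acc)
  genes_per_chrom <- diff(round(seq(0, config$n_genes,
                                    length.out = config$n_chrom + 1)))
  gene_chrom <- rep(paste0("chr", seq_len(config$n_chrom)), genes_per_chrom)
  chrom_cursor <- stats::setNames(rep(0L, config$n_chrom),
                                  paste0("chr", seq_len(config$n_chrom)))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  chrom <- pos <- integer(0)
  snp_chr <- character(0)
  calls_cols <- list()
  gene_rows <- list()
  truth_genes <- list()
  maf_targets <- numeric(0)
  for (g in seq_len(config$n_genes)) {
    cc <- gene_chrom[g]
    L <- sample(config$snps_per_gene[1]:config$snps_per_gene[2], 1)
    H <- sample(config$haps_per_gene[1]:config$haps_per_gene[2], 1)
    H <- min(H, 2^L)                      # L SNPs support at most 2^L strings
    q0 <- .rdirichlet1(H)
    if (stats::runif(1) < config$divergence) {
      q1 <- .rdirichlet1(H)
      q2 <- .rdirichlet1(H)
    } else {
      q1 <- q2 <- q0
    }
    qmix <- (config$subpop_sizes[1] * q1 + config$subpop_sizes[2] * q2) / n
    ## founder alt patterns, one subset of founders per SNP
    pat <- matrix(FALSE, nrow = H, ncol = L)
    used_patterns <- list()
    m_targets <- stats::runif(L, config$maf_spectrum[1],
                              config$maf_spectrum[2])
    for (l in seq_len(L)) {
      carriers <- .pick_carriers(qmix, m_targets[l], used_patterns)
      used_patterns[[l]] <- seq_len(H) %in% carriers
      pat[carriers, l] <- TRUE
    }
    ## accession founder index by subpopulation
    z <- integer(n)
    z[subpop == 1] <- sample.int(H, config$subpop_sizes[1], replace = TRUE,
                                 prob = q1)
    z[subpop == 2] <- sample.int(H, config$subpop_sizes[2], replace = TRUE,
                                 prob = q2)
    alt_mat <- pat[z, , drop = FALSE]     # accessions x L, uncorrupted
    g_calls <- matrix(ifelse(alt_mat, CALL_ALT_HOM, CALL_REF_HOM),
                      nrow = n)
    u <- matrix(stats::runif(n * L), nrow = n)
    g_calls[u < config$missing_rate + config$het_rate] <- CALL_HET
    g_calls[u < config$missing_rate] <- NA_integer_
    ## coordinates: genes tile the chromosome with 2 kb gaps
    start <- chrom_cursor[cc] + 2000L
    offs <- cumsum(sample(30:150, L, replace = TRUE))
    p <- start + offs
    end <- p[L] + 100L
    chrom_cursor[cc] <- end
    snp_chr <- c(snp_chr, rep(cc, L))
    pos <- c(pos, p)
    maf_targets <- c(maf_targets, m_targets)
    calls_cols[[g]] <- g_calls
    gene_rows[[g]] <- data.frame(gene_id = gene_ids[g], chrom = cc,
                                 start = start, end = end, strand = "+",
                                 stringsAsFactors = FALSE)
    ## planted truth: classes = distinct realized (uncorrupted) strings,
    ## ordered by descending count then first occurrence
    keys <- apply(alt_mat, 1, paste, collapse = "")
    defs <- unique(keys)
    cnt <- as.integer(table(factor(keys, levels = defs)))
    ord <- order(-cnt, seq_along(defs))
    class_of <- match(keys, defs[ord])
    truth_genes[[gene_ids[g]]] <- list(
      n_founders = H, founder_of = stats::setNames(z, acc),
      class_of = stats::setNames(class_of, acc),
      n_classes = length(defs),
      class_counts = cnt[ord],
      founder_alt = pat)
  }
  calls <- do.call(cbind, calls_cols)
  ref <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  snp_ids <- paste0("S", match(snp_chr, unique(snp_chr)), "_", pos)
  panel <- genotype_panel(acc, snp_ids, snp_chr, pos, ref, alt, calls)
  genes <- do.call(rbind, gene_rows)
  list(panel = panel, genes = genes,
       truth = list(subpop = subpop, genes = truth_genes,
                    maf_targets = stats::setNames(maf_targets, snp_ids),
                    seed = config$seed))
}

#' Simulate traits with planted haplotype effects
#'
#' Each trait is a baseline of 1.0 (% scale) plus an optional additive
#' shift for the second subpopulation, Gaussian noise, and for each
#' causal entry a haplotype-class effect scaled so the realized fraction
#' of trait variance it explains approximates the target `fve`
#' (effect variance is scaled against the structure + noise background).
#'
#' @param panel output of [simulate_panel()] (`$panel`).
#' @param truth output of [simulate_panel()] (`$truth`).
#' @param config the same [sim_config()].
#' @return a `trait_table` with attribute `"realized"`: a `data.frame`
#'   (`gene_id`, `trait`, `fve_target`, `fve_realized`) for each causal
#'   entry.
#' @export
simulate_traits <- function(panel, truth, config) {
  set.seed(config$seed + 1L)
  acc <- panel$accession_ids
  n <- length(acc)
  shift <- config$structure_effect * (truth$subpop[acc] == 2)
  tm <- matrix(NA_real_, nrow = n, ncol = length(config$trait_names),
               dimnames = list(acc, config$trait_names))
  realized <- list()
  for (tr in config$trait_names) {
    b <- shift + stats::rnorm(n, 0, config$noise_sd)
    y <- 1.0 + b
    entries <- Filter(function(e) e$trait == tr, config$causal_genes)
    for (e in entries) {
      gid <- if (is.character(e$gene)) e$gene else
        names(truth$genes)[e$gene]
      tg <- truth$genes[[gid]]
      if (is.null(tg)) stop("causal gene not simulated: ", gid)
      if (!is.null(e$causal_snp)) {
        g_raw <- as.numeric(tg$founder_alt[tg$founder_of[acc], e$causal_snp])
      } else {
        eff <- if (!is.null(e$effects)) e$effects else
          stats::rnorm(tg$n_classes)
        if (length(eff) != tg$n_classes)
          stop("effects length != realized classes for ", gid)
        g_raw <- eff[tg$class_of[acc]]
      }
      vg <- stats::var(g_raw)
      if (vg == 0)
        stop("causal gene ", gid, " realized fewer than 2 effect classes; ",
             "regenerate with a different seed")
      vb <- stats::var(b)
      if (vb > 0) {
        ## scale s so the *realized* explained variance — the sample R^2
        ## of the trait regressed on the causal effect — equals the
        ## target exactly, accounting for the sampling covariance c
        ## between the effect and the background (noise + structure
        ## shift). With u = cov(g, y) = s*vg + c,
        ## R^2 = u^2 / (u^2 + vg*vb - c^2), hence
        ## u = sqrt(f/(1-f) * (vg*vb - c^2)) and s = (u - c)/vg.
        c_gb <- stats::cov(g_raw, b)
        u <- sqrt(e$fve / (1 - e$fve) * max(vg * vb - c_gb^2, 0))
        s <- (u - c_gb) / vg
      } else {
        ## no background variance (noiseless, unstructured): effects enter
        ## unscaled and the class signal is the whole trait
        s <- 1
      }

      comp <- s * (g_raw - mean(g_raw))
      y <- y + comp
      realized[[length(realized) + 1]] <- data.frame(
        gene_id = gid, trait = tr, fve_target = e$fve,
        fve_realized = if (vb > 0)
          suppressWarnings(stats::cor(g_raw, y))^2 else
            stats::var(comp) / stats::var(y),
        stringsAsFactors = FALSE)
    }
    tm[, tr] <- pmax(y, 0)   # contents are non-negative by definition
  }
  df <- data.frame(accession_id = acc, tm, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  class(df) <- c("trait_table", "data.frame")
  attr(df, "realized") <- if (length(realized))
    do.call(rbind, realized) else
      data.frame(gene_id = character(), trait = character(),
                 fve_target = numeric(), fve_realized = numeric())
  df
}

#' Write a complete fixture bundle
#'
#' Simulates a panel plus traits and writes `panel.vcf`, `genes.gff3`,
#' `traits.csv`, `truth.json` and `config.json` into `outdir`. The
#' bundle is the standard end-to-end input of the test suite and the
#' pipeline.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()].
#' @return named character vector of the file paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(config)
  traits <- simulate_traits(sim$panel, sim$truth, config)
  paths <- c(vcf = file.path(outdir, "panel.vcf"),
             gff = file.path(outdir, "genes.gff3"),
             traits = file.path(outdir, "traits.csv"),
             truth = file.path(outdir, "truth.json"),
             config = file.path(outdir, "config.json"))
  write_vcf(sim$panel, paths["vcf"])
  write_gff3(sim$genes, paths["gff"])
  write_trait_table(traits, paths["traits"])
  truth_json <- list(
    subpop = as.list(sim$truth$subpop),
    n_classes = lapply(sim$truth$genes, `[[`, "n_classes"),
    class_of = lapply(sim$truth$genes, function(g) as.list(g$class_of)),
    realized_fve = attr(traits, "realized"),
    seed = config$seed)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
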