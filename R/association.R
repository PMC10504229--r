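## association: per-gene haplotype-class F-test with PC covariates,
## genomic inflation, within-gene single-SNP scan, key-variant call.

#' Scan configuration
#'
#' @param alpha significance threshold on the gene-level p-value
#'   (default `1e-4`).
#' @param Q number of principal-component covariates (default 2).
#' @param min_class_count rare haplotype-class threshold (default 5).
#' @param seed integer RNG seed used by any stochastic step.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(alpha = 1e-4, Q = 2, min_class_count = 5, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, Q >= 0)
  structure(list(alpha = alpha, Q = as.integer(Q),
                 min_class_count = as.integer(min_class_count),
                 seed = as.integer(seed)),
            class = "scan_config")
}

## QR-based residual sum of squares with rank detection.
## Returns list(rss, rank). X must already include the intercept.
.rss_qr <- function(X, y) {
  qx <- qr(X)
  list(rss = sum(qr.resid(qx, y)^2), rank = qx$rank)
}

#' Haplotype-class association test for one gene and one trait
#'
#' Ordinary least squares of the trait on an intercept, `Q` principal
#' components, and `n_classes - 1` haplotype-class indicators (the most
#' frequent class, Hap1, is the reference). The gene-level statistic is
#' the F-test of the joint null that all class coefficients are zero,
#' i.e. full model against the PCs-only reduced model:
#' `F = ((RSS0 - RSS1)/df1) / (RSS1/df2)` with `df1` the number of
#' independent class columns and `df2 = n_used - rank(full design)`.
#'
#' Accessions used are the intersection of class-assigned accessions,
#' accessions with a non-missing trait value, and (when `Q > 0`) rows of
#' `pc_coords`. Classes emptied by the intersection are not counted in
#' `n_classes_tested`. A design made singular by confounding between
#' classes and PCs has its collinear columns dropped and is flagged.
#'
#' @param trait_values named numeric vector (names = accession ids).
#' @param haplotype_table a `haplotype_table` (after any rare-class
#'   exclusion).
#' @param pc_coords accession x PC matrix with rownames, or `NULL` when
#'   `Q = 0`.
#' @param Q number of PC covariates.
#' @param alpha significance threshold (default `1e-4`).
#' @param trait name of the trait (carried into the record).
#' @return a one-row `data.frame` with columns `gene_id`, `trait`,
#'   `chrom`, `n_classes_tested`, `n_used`, `F`, `df1`, `df2`,
#'   `p_value`, `significant`, `degenerate`, `collinear`, `untestable`,
#'   `class_means` (semicolon-separated `Hap=mean` pairs).
#' @export
fit_haplotype_model <- function(trait_values, haplotype_table, pc_coords,
                                Q = 2, alpha = 1e-4, trait = "trait") {
  ht <- haplotype_table
  rec <- data.frame(
    gene_id = ht$gene_id, trait = trait, chrom = ht$chrom,
    n_classes_tested = NA_integer_, n_used = NA_integer_,
    F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
    p_value = NA_real_, significant = FALSE, degenerate = FALSE,
    collinear = FALSE, untestable = TRUE, class_means = NA_character_,
    stringsAsFactors = FALSE)
  assigned <- names(ht$assignment)[!is.na(ht$assignment)]
  used <- intersect(assigned, names(trait_values)[!is.na(trait_values)])
  if (Q > 0) {
    if (is.null(pc_coords)) stop("Q > 0 but pc_coords is NULL")
    used <- intersect(used, rownames(pc_coords))
  }
  if (length(used) == 0) return(rec)
  y <- as.numeric(trait_values[used])
  cls <- ht$assignment[used]
  present <- sort(unique(cls))
  k <- length(present)
  rec$n_classes_tested <- k
  rec$n_used <- length(used)
  means <- tapply(y, cls, mean)
  rec$class_means <- paste(sprintf("Hap%d=%.6g", as.integer(names(means)),
                                   means), collapse = ";")
  if (k < 2) return(rec)
  X0 <- matrix(1, nrow = length(used), ncol = 1)
  if (Q > 0)
    X0 <- cbind(X0, pc_coords[used, seq_len(min(Q, ncol(pc_coords))),
                              drop = FALSE])
  f <- factor(cls, levels = present)
  D <- stats::model.matrix(~f)[, -1, drop = FALSE]  # Hap-reference coding
  r0 <- .rss_qr(X0, y)
  r1 <- .rss_qr(cbind(X0, D), y)
  df1 <- r1$rank - r0$rank
  df2 <- length(used) - r1$rank
  rec$collinear <- r1$rank < ncol(X0) + ncol(D)
  if (df1 < 1 || df2 < 1) return(rec)
  rec$untestable <- FALSE
  rec$df1 <- df1
  rec$df2 <- df2
  tol <- 1e-12 * max(1, sum(y^2))
  if (r1$rss <= tol) {
    rec$degenerate <- TRUE
    if (r0$rss <= tol) {
      ## trait constant given covariates: no information, no call
      rec$untestable <- TRUE
      return(rec)
    }
    ## perfect fit by the classes: p indistinguishable from 0
    rec$F <- Inf
    rec$p_value <- .Machine$double.xmin
    rec$significant <- rec$p_value < alpha
    return(rec)
  }
  rec$F <- ((r0$rss - r1$rss) / df1) / (r1$rss / df2)
  rec$p_value <- stats::pf(rec$F, df1, df2, lower.tail = FALSE)
  rec$significant <- rec$p_value < alpha
  rec
}

#' Genome-wide haplotype association scan
#'
#' Runs [fit_haplotype_model()] for every testable gene x trait pair.
#' Results are ordered by (chromosome, gene start, trait); gene start and
#' midpoint come from `genes` when supplied, otherwise from the gene's
#' SNP span.
#'
#' @param panel a [genotype_panel()] (QC-filtered).
#' @param gene_snp_index from [assign_snps_to_genes()].
#' @param haplotype_tables named list from [build_all_haplotypes()].
#' @param traits a `trait_table`.
#' @param structure a `structure_result` (may be `NULL` when `config$Q == 0`).
#' @param config a [scan_config()].
#' @param genes optional gene models (for coordinates/ordering).
#' @return `data.frame` of gene association records, one row per
#'   testable gene x trait, plus columns `gene_start`, `gene_end`,
#'   `gene_mid`.
#' @export
run_gwha_scan <- function(panel, gene_snp_index, haplotype_tables, traits,
                          structure, config = scan_config(), genes = NULL) {
  tm <- trait_matrix(traits)
  pcs <- if (!is.null(structure)) structure$pc_coords else NULL
  testable <- Filter(function(t) !t$untestable, haplotype_tables)
  if (length(testable) == 0)
    stop("no testable genes: ", length(haplotype_tables), " gene(s), ",
         sum(vapply(haplotype_tables, `[[`, logical(1), "untestable")),
         " untestable after rare-class exclusion")
  rows <- vector("list", length(testable) * ncol(tm))
  i <- 0
  for (ht in testable) {
    for (tr in colnames(tm)) {
      i <- i + 1
      rows[[i]] <- fit_haplotype_model(tm[, tr], ht, pcs, Q = config$Q,
                                       alpha = config$alpha, trait = tr)
    }
  }
  res <- do.call(rbind, rows)
  ## gene coordinates
  if (!is.null(genes)) {
    gi <- match(res$gene_id, genes$gene_id)
    res$gene_start <- genes$start[gi]
    res$gene_end <- genes$end[gi]
  } else {
    span <- t(vapply(haplotype_tables[res$gene_id], function(t)
      range(panel$pos[t$snp_idx]), numeric(2)))
    res$gene_start <- span[, 1]
    res$gene_end <- span[, 2]
  }
  res$gene_mid <- (res$gene_start + res$gene_end) / 2
  chrom_rank <- match(res$chrom, unique(panel$chrom))
  res <- res[order(chrom_rank, res$gene_start, res$trait), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genomic inflation factor
#'
#' Median-based lambda: the observed p-values are transformed to 1-df
#' chi-squared quantiles and the median is divided by the theoretical
#' null median (`qchisq(0.5, 1)` = 0.4549364).
#'
#' @param p numeric vector of p-values (at least 20).
#' @return `lambda_gc`, or `NA` with a warning when fewer than 20
#'   p-values are supplied.
#' @export
genomic_inflation <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) < 20) {
    warning("fewer than 20 p-values; lambda not computed")
    return(NA_real_)
  }
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Single-SNP scan within selected genes
#'
#' For each requested (gene, trait) pair, every gene-body SNP is tested
#' by OLS of the trait on an intercept, `Q` PCs and the SNP dosage
#' (0/1/2; accessions with a missing call at the SNP are dropped). The
#' two-sided p-value of the dosage coefficient is reported. SNPs that
#' are monomorphic among the used accessions are flagged `skipped`.
#'
#' @param panel a [genotype_panel()].
#' @param gene_snp_index from [assign_snps_to_genes()].
#' @param traits a `trait_table`.
#' @param structure a `structure_result` (or `NULL` for `Q = 0`).
#' @param config a [scan_config()].
#' @param pairs `data.frame` with columns `gene_id`, `trait`; typically
#'   the significant rows of [run_gwha_scan()].
#' @return `data.frame` with columns `snp_id`, `gene_id`, `trait`,
#'   `chrom`, `pos`, `ref`, `alt`, `beta`, `p_value`, `skipped`,
#'   `is_key_variant` (all `FALSE`; set by [key_variant_per_gene()]).
#' @export
run_snp_scan <- function(panel, gene_snp_index, traits, structure,
                         config = scan_config(), pairs) {
  stopifnot(all(c("gene_id", "trait") %in% names(pairs)))
  tm <- trait_matrix(traits)
  pcs <- if (!is.null(structure)) structure$pc_coords else NULL
  Q <- config$Q
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[r]
    tr <- pairs$trait[r]
    snp_idx <- gene_snp_index[[g]]
    if (is.null(snp_idx)) next
    yfull <- tm[, tr]
    for (j in snp_idx) {
      dose <- panel$calls[, j]
      used <- names(dose)[!is.na(dose)]
      used <- intersect(used, rownames(tm)[!is.na(yfull)])
      if (Q > 0) used <- intersect(used, rownames(pcs))
      rec <- data.frame(
        snp_id = panel$snp_ids[j], gene_id = g, trait = tr,
        chrom = panel$chrom[j], pos = panel$pos[j],
        ref = panel$ref[j], alt = panel$alt[j],
        beta = NA_real_, p_value = NA_real_, skipped = TRUE,
        is_key_variant = FALSE, stringsAsFactors = FALSE)
      d <- as.numeric(dose[used])
      if (length(used) >= 3 && stats::var(d) > 0) {
        X <- cbind(1, if (Q > 0)
          pcs[used, seq_len(min(Q, ncol(pcs))), drop = FALSE], d)
        y <- yfull[used]
        qx <- qr(X)
        if (qx$rank == ncol(X) && length(used) > ncol(X)) {
          cf <- qr.coef(qx, y)
          res <- qr.resid(qx, y)
          df <- length(used) - ncol(X)
          s2 <- sum(res^2) / df
          XtXinv <- chol2inv(chol(crossprod(X)))
          se <- sqrt(s2 * XtXinv[ncol(X), ncol(X)])
          if (is.finite(se) && se > 0) {
            tstat <- cf[length(cf)] / se
            rec$beta <- cf[length(cf)]
            rec$p_value <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
            rec$skipped <- FALSE
          } else if (s2 <= 1e-24) {
            ## perfect fit: dosage explains the trait exactly
            rec$beta <- cf[length(cf)]
            rec$p_value <- .Machine$double.xmin
            rec$skipped <- FALSE
          }
        }
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(), gene_id = character(),
               trait = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), beta = numeric(),
               p_value = numeric(), skipped = logical(),
               is_key_variant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag the key natural variant of a gene
#'
#' Within one (gene, trait), the scored SNP with the lowest p-value is
#' flagged as the key natural variant; ties are broken by the smaller
#' genomic position.
#'
#' @param snp_results output of [run_snp_scan()].
#' @param gene_id,trait the pair to resolve.
#' @return `snp_results` with `is_key_variant` set to `TRUE` for exactly
#'   one row of the pair (or unchanged, with a warning, when no SNP was
#'   scored).
#' @export
key_variant_per_gene <- function(snp_results, gene_id, trait) {
  sel <- which(snp_results$gene_id == gene_id &
                 snp_results$trait == trait & !snp_results$skipped &
                 is.finite(snp_results$p_value))
  if (length(sel) == 0) {
    warning("no scored SNPs for ", gene_id, " x ", trait)
    return(snp_results)
  }
  best <- sel[order(snp_results$p_value[sel], snp_results$pos[sel])][1]
  snp_results$is_key_variant[best] <- TRUE
  snp_results
}

#' Flag key variants for every (gene, trait) pair present
#' @param snp_results output of [run_snp_scan()].
#' @return `snp_results` with `is_key_variant` resolved per pair.
#' @export
key_variants_all <- function(snp_results) {
  if (nrow(snp_results) == 0) return(snp_results)
  prs <- unique(snp_results[c("gene_id", "trait")])
  for (r in seq_len(nrow(prs)))
    snp_results <- key_variant_per_gene(snp_results, prs$gene_id[r],
                                        prs$trait[r])
  snp_results
}

#' Export Manhattan and QQ plot data
#'
#' Writes `<prefix>_manhattan.tsv` (chrom, position = gene midpoint,
#' neg_log10_p, trait) and `<prefix>_qq.tsv` (expected, observed
#' -log10 quantiles; `expected[i] = -log10((i - 0.5)/n)` with p-values
#' sorted ascending).
#'
#' @param results output of [run_gwha_scan()].
#' @param path_prefix path prefix for the two TSVs.
#' @return character vector of the two paths, invisibly.
#' @export
export_manhattan_qq <- function(results, path_prefix) {
  ok <- is.finite(results$p_value)
  man <- data.frame(chrom = results$chrom[ok],
                    position = results$gene_mid[ok],
                    neg_log10_p = -log10(results$p_value[ok]),
                    trait = results$trait[ok])
  p_man <- paste0(path_prefix, "_manhattan.tsv")
  utils::write.table(man, p_man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- sort(results$p_value[ok])
  n <- length(p)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = -log10(p))
  p_qq <- paste0(path_prefix, "_qq.tsv")
  utils::write.table(qq, p_qq, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_man, p_qq))
}
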