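## popstructure: PCA on thinned dosages, k-means subpopulation labels,
## centered-IBS (VanRaden-scaled) kinship.

#' Numeric dosage matrix from a panel
#'
#' Calls are coded 0 (hom ref), 1 (het), 2 (hom alt); missing calls are
#' imputed with the per-SNP mean dosage of the called accessions. SNPs
#' with no called accession in the subset are dropped with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param snp_subset integer indices of SNPs to use (default: all).
#' @return numeric matrix, accessions x SNPs, entries in `[0, 2]`, with
#'   attribute `"dropped"` counting all-missing SNPs removed.
#' @export
dosage_matrix <- function(panel, snp_subset = seq_along(panel$snp_ids)) {
  if (length(snp_subset) == 0) stop("empty SNP subset")
  d <- panel$calls[, snp_subset, drop = FALSE]
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  all_miss <- !is.finite(mu)
  if (any(all_miss)) {
    warning(sum(all_miss), " all-missing SNP(s) dropped from dosage matrix")
    d <- d[, !all_miss, drop = FALSE]
    mu <- mu[!all_miss]
  }
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx)) d[na_idx] <- mu[na_idx[, 2]]
  attr(d, "dropped") <- sum(all_miss)
  d
}

#' Principal components of a dosage matrix
#'
#' Singular-value decomposition of the column-centered dosage matrix.
#' Scores are `U %*% diag(d)`. The sign of each component is fixed by
#' making its largest-magnitude SNP loading positive, so results are
#' reproducible across platforms.
#'
#' @param dosage accession x SNP numeric matrix ([dosage_matrix()]).
#' @param n_components number of PCs to retain (default 10; truncated to
#'   the matrix rank with a warning if larger).
#' @return object of class `structure_result`: `pc_coords` (accession x Q),
#'   `eigenvalues` (d^2/(n-1), non-increasing), `variance_explained`
#'   (fractions of total variance), `cluster_labels` (`NULL` until
#'   [cluster_accessions()] is run).
#' @export
pca_structure <- function(dosage, n_components = 10) {
  if (nrow(dosage) < 2 || ncol(dosage) < 2)
    stop("need at least 2 accessions and 2 SNPs")
  W <- scale(dosage, center = TRUE, scale = FALSE)
  sv <- svd(W)
  tol <- max(dim(W)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == 0) stop("dosage matrix has rank 0 (no polymorphism)")
  q <- n_components
  if (q > rank) {
    warning("n_components = ", n_components, " exceeds rank ", rank,
            "; truncated")
    q <- rank
  }
  U <- sv$u[, seq_len(q), drop = FALSE]
  V <- sv$v[, seq_len(q), drop = FALSE]
  d <- sv$d[seq_len(q)]
  for (j in seq_len(q)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  coords <- U %*% diag(d, nrow = q)
  dimnames(coords) <- list(rownames(dosage), paste0("PC", seq_len(q)))
  total <- sum(sv$d^2)
  structure(
    list(pc_coords = coords,
         eigenvalues = d^2 / (nrow(dosage) - 1),
         variance_explained = d^2 / total,
         cluster_labels = NULL),
    class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("structure_result: %d accessions, %d PC(s); PC1 %.1f%% var\n",
              nrow(x$pc_coords), ncol(x$pc_coords),
              100 * x$variance_explained[1]))
  invisible(x)
}

#' Cluster accessions into subpopulations
#'
#' k-means on the leading principal components (the first
#' `max(3, ceiling(log2(K)))` PCs, or fewer if not available). Cluster
#' labels are renumbered so that label 1 is the largest cluster.
#' Deterministic given `seed`.
#'
#' @param structure a `structure_result`.
#' @param K number of subpopulations (default 2).
#' @param seed integer RNG seed (required).
#' @return named integer vector of labels in `1..K`, in accession order.
#' @export
cluster_accessions <- function(structure, K = 2, seed) {
  coords <- structure$pc_coords
  n <- nrow(coords)
  if (K > n) stop("K = ", K, " exceeds number of accessions (", n, ")")
  labs <- rep(1L, n)
  if (K > 1) {
    npc <- min(ncol(coords), max(3, ceiling(log2(K))))
    set.seed(as.integer(seed))
    km <- stats::kmeans(coords[, seq_len(npc), drop = FALSE],
                        centers = K, nstart = 25, iter.max = 100)
    sizes <- tabulate(km$cluster, K)
    relabel <- match(seq_len(K), order(-sizes, seq_len(K)))
    labs <- relabel[km$cluster]
  }
  stats::setNames(as.integer(labs), rownames(coords))
}

#' Centered-IBS (VanRaden-scaled) kinship matrix
#'
#' Each dosage column is centered by its mean; the kinship is
#' `K = W W' / c` with `c = sum_l 2 p_l (1 - p_l)` and
#' `p_l = column mean / 2`, the usual genomic-relationship scaling for
#' centered identity-by-state.
#'
#' @param dosage accession x SNP numeric matrix ([dosage_matrix()]).
#' @return symmetric accession x accession numeric matrix.
#' @export
centered_ibs_kinship <- function(dosage) {
  if (nrow(dosage) < 2) stop("need at least 2 accessions")
  p <- colMeans(dosage) / 2
  cc <- sum(2 * p * (1 - p))
  if (cc <= 0) stop("no polymorphism: scaling constant is zero")
  W <- scale(dosage, center = TRUE, scale = FALSE)
  K <- tcrossprod(W) / cc
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(dosage), rownames(dosage))
  K
}

#' Write PC coordinates as TSV
#' @param structure a `structure_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  df <- data.frame(accession_id = rownames(structure$pc_coords),
                   structure$pc_coords, check.names = FALSE)
  if (!is.null(structure$cluster_labels))
    df$cluster <- structure$cluster_labels[df$accession_id]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
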