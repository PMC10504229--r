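test_that("dosage matrix codes 0/1/2 and mean-imputes missing", {
  calls <- rbind(c(0L, 0L), c(2L, 1L), c(NA, 2L))
  p <- genotype_panel(paste0("A", 1:3), c("s1", "s2"), c("chr1", "chr1"),
                      c(10L, 20L), c("A", "C"), c("G", "T"), calls)
  d <- dosage_matrix(p)
  expect_equal(unname(d[, 1]), c(0, 2, 1))   # mean of {0, 2}
  expect_equal(unname(d[, 2]), c(0, 1, 2))   # exact coding, no missing
  ## hand-coded 4 x 3 matrix
  calls2 <- rbind(c(0L, 2L, NA), c(2L, 2L, 0L), c(0L, NA, 0L), c(2L, 0L, 0L))
  p2 <- genotype_panel(paste0("B", 1:4), paste0("s", 1:3), rep("chr1", 3),
                       c(1L, 2L, 3L), rep("A", 3), rep("G", 3), calls2)
  d2 <- dosage_matrix(p2)
  expect_equal(unname(d2),
               rbind(c(0, 2, 0), c(2, 2, 0), c(0, 4 / 3, 0), c(2, 0, 0)),
               ignore_attr = TRUE)
  ## all-missing SNP dropped with warning
  calls3 <- cbind(c(0L, 2L), c(NA, NA))
  p3 <- genotype_panel(paste0("C", 1:2), c("s1", "s2"), rep("chr1", 2),
                       c(1L, 2L), rep("A", 2), rep("G", 2), calls3)
  expect_warning(d3 <- dosage_matrix(p3), "all-missing")
  expect_equal(ncol(d3), 1L)
})

test_that("PC1 separates two fully diverged blocks", {
  d <- rbind(matrix(0, 5, 100), matrix(2, 5, 100))
  rownames(d) <- paste0("A", 1:10)
  s <- suppressWarnings(pca_structure(d, n_components = 2))
  expect_gt(s$variance_explained[1], 0.999)
  expect_true(all(sign(s$pc_coords[1:5, 1]) != sign(s$pc_coords[6:10, 1])))
})

test_that("permuting accessions permutes PC rows identically", {
  set.seed(4)
  d <- matrix(sample(0:2, 8 * 20, replace = TRUE), 8, 20)
  rownames(d) <- paste0("A", 1:8)
  s <- pca_structure(d, 3)
  perm <- sample(8)
  s2 <- pca_structure(d[perm, ], 3)
  expect_equal(unname(s2$pc_coords), unname(s$pc_coords[perm, ]),
               tolerance = 1e-9)
})

test_that("PCA matches a dense eigendecomposition oracle up to sign", {
  set.seed(8)
  d <- matrix(runif(8 * 20, 0, 2), 8, 20)
  rownames(d) <- paste0("A", 1:8)
  q <- 5
  s <- pca_structure(d, q)
  W <- scale(d, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(W), symmetric = TRUE)
  for (j in seq_len(q)) {
    scores_o <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_equal(abs(unname(s$pc_coords[, j])), abs(scores_o),
                 tolerance = 1e-8)
  }
  expect_equal(s$variance_explained[seq_len(q)],
               (ev$values / sum(ev$values))[seq_len(q)], tolerance = 1e-8)
  expect_true(all(diff(s$eigenvalues) <= 1e-12))
  ## isometry: with Q = rank, PC coordinates reproduce pairwise distances
  full <- suppressWarnings(pca_structure(d, n_components = 8))
  expect_equal(as.matrix(dist(full$pc_coords)), as.matrix(dist(W)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("k-means recovers planted subpopulations and is deterministic", {
  cfg <- sim_config(n_accessions = 60, subpop_sizes = c(20, 40),
                    divergence = 1, n_genes = 80, snps_per_gene = c(5, 15),
                    missing_rate = 0, het_rate = 0, seed = 17)
  sim <- simulate_panel(cfg)
  d <- dosage_matrix(sim$panel)
  s <- pca_structure(d, 4)
  labs <- cluster_accessions(s, K = 2, seed = 5)
  truth <- sim$truth$subpop
  agree <- max(mean(labs == truth), mean(labs == 3 - truth))
  expect_equal(agree, 1)
  ## label 1 is the largest cluster
  expect_gte(sum(labs == 1), sum(labs == 2))
  expect_identical(labs, cluster_accessions(s, K = 2, seed = 5))
  expect_identical(unname(cluster_accessions(s, K = 1, seed = 5)),
                   rep(1L, 60))
  expect_error(cluster_accessions(s, K = 99, seed = 5), "exceeds")
})

test_that("centered-IBS kinship matches the pencil-and-paper oracle", {
  d <- rbind(c(0, 2), c(2, 0), c(0, 0))
  rownames(d) <- paste0("A", 1:3)
  K <- centered_ibs_kinship(d)
  expect_equal(unname(K),
               rbind(c(2.5, -2, -0.5), c(-2, 2.5, -0.5), c(-0.5, -0.5, 1)),
               tolerance = 1e-12)
  ## identical accessions have identical rows, K[1,2] = K[1,1]
  d2 <- rbind(c(0, 2, 2), c(0, 2, 2), c(2, 0, 0))
  rownames(d2) <- paste0("B", 1:3)
  K2 <- centered_ibs_kinship(d2)
  expect_equal(K2[1, 2], K2[1, 1])
  expect_equal(K2[1, ], K2[2, ], ignore_attr = TRUE)
  ## symmetry for random input
  set.seed(6)
  d3 <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  rownames(d3) <- paste0("C", 1:6)
  K3 <- centered_ibs_kinship(d3)
  expect_lt(max(abs(K3 - t(K3))), 1e-12)
  expect_error(centered_ibs_kinship(matrix(2, 3, 4)), "no polymorphism")
})

test_that("within-cluster kinship exceeds between-cluster kinship", {
  ok <- 0
  for (seed in 1:20) {
    cfg <- sim_config(n_accessions = 40, subpop_sizes = c(15, 25),
                      divergence = 0.8, n_genes = 25,
                      snps_per_gene = c(1, 8), missing_rate = 0,
                      het_rate = 0, seed = 100 + seed)
    sim <- simulate_panel(cfg)
    K <- centered_ibs_kinship(dosage_matrix(sim$panel))
    same <- outer(sim$truth$subpop, sim$truth$subpop, "==")
    diag(same) <- NA
    within <- mean(K[which(same)], na.rm = TRUE)
    between <- mean(K[which(!same)], na.rm = TRUE)
    if (within > between) ok <- ok + 1
  }
  expect_equal(ok, 20L)
})
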