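test_that("config validation catches infeasible settings", {
  expect_error(sim_config(seed = 1, subpop_sizes = c(10, 10),
                          n_accessions = 30), "sum to n_accessions")
  expect_error(sim_config(n_accessions = 20, subpop_sizes = c(5, 15)),
               "seed")
})

test_that("same seed gives byte-identical fixtures, different seeds differ", {
  cfg <- sim_config(n_accessions = 20, subpop_sizes = c(8, 12),
                    n_genes = 10, snps_per_gene = c(1, 8), seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(d1, cfg)
  write_fixture_bundle(d2, cfg)
  expect_identical(readLines(file.path(d1, "panel.vcf")),
                   readLines(file.path(d2, "panel.vcf")))
  cfg2 <- sim_config(n_accessions = 20, subpop_sizes = c(8, 12),
                     n_genes = 10, snps_per_gene = c(1, 8), seed = 8)
  d3 <- withr::local_tempdir()
  write_fixture_bundle(d3, cfg2)
  expect_false(identical(readLines(file.path(d1, "panel.vcf")),
                         readLines(file.path(d3, "panel.vcf"))))
})

test_that("fixture bundle parses back through io_formats without loss", {
  cfg <- sim_config(n_accessions = 10, subpop_sizes = c(4, 6),
                    n_genes = 20, snps_per_gene = c(1, 6), seed = 3)
  d <- withr::local_tempdir()
  paths <- write_fixture_bundle(d, cfg)
  sim <- simulate_panel(cfg)
  p <- read_vcf(paths["vcf"])
  expect_identical(unname(p$calls), unname(sim$panel$calls))
  expect_identical(p$pos, sim$panel$pos)
  g <- read_gff3(paths["gff"])
  expect_equal(g, sim$genes, ignore_attr = TRUE)
  tt <- read_trait_table(paths["traits"])
  expect_equal(dim(tt), c(10L, 18L))   # accession_id + 17 traits
  expect_identical(trait_names(tt), aa_trait_names())
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$seed, 3L)
})

test_that("divergence drives structure strength", {
  cfg0 <- sim_config(n_accessions = 40, subpop_sizes = c(15, 25),
                     divergence = 0, n_genes = 30, snps_per_gene = c(1, 8),
                     missing_rate = 0, het_rate = 0, seed = 19)
  cfg1 <- sim_config(n_accessions = 40, subpop_sizes = c(15, 25),
                     divergence = 1, n_genes = 30, snps_per_gene = c(1, 8),
                     missing_rate = 0, het_rate = 0, seed = 19)
  s0 <- pca_structure(dosage_matrix(simulate_panel(cfg0)$panel), 3)
  s1 <- pca_structure(dosage_matrix(simulate_panel(cfg1)$panel), 3)
  expect_gt(s1$variance_explained[1], s0$variance_explained[1])
  ## divergence 1: k-means on PCs recovers the planted split exactly
  sim <- simulate_panel(cfg1)
  labs <- cluster_accessions(pca_structure(dosage_matrix(sim$panel), 3),
                             K = 2, seed = 2)
  truth <- sim$truth$subpop
  expect_equal(max(mean(labs == truth), mean(labs == 3 - truth)), 1)
})

test_that("realized MAF tracks the configured spectrum", {
  cfg <- sim_config(n_accessions = 164, n_genes = 420,
                    snps_per_gene = c(20, 30), haps_per_gene = c(4, 8),
                    missing_rate = 0, het_rate = 0, seed = 23)
  sim <- simulate_panel(cfg)
  qc <- compute_snp_qc(sim$panel)
  expect_gte(length(qc$maf), 1e4)
  ## realized frequencies approximate their per-SNP targets
  err <- abs(qc$maf - pmin(sim$truth$maf_targets, 0.5))
  expect_lt(mean(err), 0.1)
  ## and the bulk of the spectrum is covered
  expect_gt(mean(qc$maf >= 0.05 & qc$maf <= 0.5), 0.7)
  expect_gt(stats::cor(qc$maf, sim$truth$maf_targets), 0.5)
})

test_that("planted traits hit their explained-variance targets", {
  dev <- numeric(50)
  for (i in 1:50) {
    cfg <- sim_config(n_accessions = 164, n_genes = 5,
                      snps_per_gene = c(3, 8), structure_effect = 0.2,
                      causal_genes = list(list(gene = 2, trait = "Lys",
                                               fve = 0.25)),
                      seed = 300 + i)
    sim <- simulate_panel(cfg)
    tr <- simulate_traits(sim$panel, sim$truth, cfg)
    dev[i] <- attr(tr, "realized")$fve_realized - 0.25
  }
  expect_lt(max(abs(dev)), 0.05)
})

test_that("noiseless single causal gene makes the trait a class function", {
  cfg <- sim_config(n_accessions = 60, subpop_sizes = c(20, 40),
                    n_genes = 3, snps_per_gene = c(2, 4), noise_sd = 0,
                    missing_rate = 0, het_rate = 0,
                    causal_genes = list(list(gene = 1, trait = "Glu",
                                             fve = 0.5)),
                    seed = 77)
  sim <- simulate_panel(cfg)
  tr <- simulate_traits(sim$panel, sim$truth, cfg)
  cls <- sim$truth$genes$G0001$class_of
  spread <- tapply(tr$Glu, cls[tr$accession_id], function(v)
    diff(range(v)))
  expect_true(all(spread < 1e-12))
  ## effects length mismatch is fatal
  bad <- sim_config(n_accessions = 60, subpop_sizes = c(20, 40),
                    n_genes = 3, snps_per_gene = c(2, 4),
                    causal_genes = list(list(gene = 1, trait = "Glu",
                                             fve = 0.5, effects = c(1, 2))),
                    seed = 77)
  sim2 <- simulate_panel(bad)
  if (sim2$truth$genes$G0001$n_classes != 2)
    expect_error(simulate_traits(sim2$panel, sim2$truth, bad),
                 "effects length")
})
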