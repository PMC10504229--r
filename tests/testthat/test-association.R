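test_that("two-class model with Q = 0 equals the pooled two-sample t-test", {
  set.seed(21)
  y <- c(rnorm(6, 0), rnorm(6, 1))
  names(y) <- sprintf("A%02d", 1:12)
  a <- stats::setNames(rep(c(1L, 2L), each = 6), names(y))
  rec <- fit_haplotype_model(y, hand_hap_table(a), NULL, Q = 0)
  tt <- t.test(y[1:6], y[7:12], var.equal = TRUE)
  expect_equal(rec$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(rec$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(rec$df1, 1L)
  expect_equal(rec$df2, 10L)
})

test_that("F, df, p match an explicit nested-RSS oracle", {
  set.seed(22)
  n <- 40
  acc <- sprintf("A%02d", 1:n)
  cls <- stats::setNames(sample(1:3, n, replace = TRUE), acc)
  pcs <- matrix(rnorm(n * 2), n, 2, dimnames = list(acc, c("PC1", "PC2")))
  y <- stats::setNames(rnorm(n) + 0.5 * (cls == 2), acc)
  rec <- fit_haplotype_model(y, hand_hap_table(cls), pcs, Q = 2)
  X0 <- cbind(1, pcs)
  X1 <- cbind(X0, cls == 2, cls == 3)
  rss0 <- oracle_rss(X0, y)
  rss1 <- oracle_rss(X1, y)
  Fo <- ((rss0 - rss1) / 2) / (rss1 / (n - 5))
  expect_equal(rec$F, Fo, tolerance = 1e-10)
  expect_equal(rec$df1, 2L)
  expect_equal(rec$df2, n - 5L)
  expect_equal(rec$p_value, pf(Fo, 2, n - 5, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(rec$n_classes_tested, 3L)
  ## class means are on the raw trait scale
  cm <- as.numeric(sub(".*=", "", strsplit(rec$class_means, ";")[[1]]))
  expect_equal(cm, as.numeric(tapply(y, cls, mean)), tolerance = 1e-5)
})

test_that("degenerate and threshold cases are flagged correctly", {
  acc <- sprintf("A%02d", 1:12)
  a <- stats::setNames(rep(c(1L, 2L), each = 6), acc)
  ## constant trait -> degenerate, no significance call
  y0 <- stats::setNames(rep(1.5, 12), acc)
  rec0 <- fit_haplotype_model(y0, hand_hap_table(a), NULL, Q = 0)
  expect_true(rec0$degenerate)
  expect_true(rec0$untestable)
  expect_false(rec0$significant)
  ## trait an exact function of class -> p ~ 0, degenerate flag
  y1 <- stats::setNames(rep(c(0, 1), each = 6), acc)
  rec1 <- fit_haplotype_model(y1, hand_hap_table(a), NULL, Q = 0)
  expect_true(rec1$degenerate)
  expect_true(rec1$significant)
  ## significance is p < alpha
  expect_true(5e-5 < 1e-4)   # the rule under test is the flag, below
  set.seed(30)
  y2 <- stats::setNames(c(rnorm(6, 0, 0.1), rnorm(6, 2, 0.1)), acc)
  rec2 <- fit_haplotype_model(y2, hand_hap_table(a), NULL, Q = 0,
                              alpha = 1e-4)
  expect_identical(rec2$significant, rec2$p_value < 1e-4)
  ## single class after intersection -> untestable
  a1 <- stats::setNames(rep(1L, 12), acc)
  rec3 <- fit_haplotype_model(y2, hand_hap_table(a1), NULL, Q = 0)
  expect_true(rec3$untestable)
})

test_that("genomic inflation matches its median identity and null range", {
  expect_warning(genomic_inflation(runif(5)), "fewer than 20")
  expect_equal(genomic_inflation(rep(0.5, 100)), 1)
  set.seed(31)
  lam <- genomic_inflation(runif(10000))
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
})

test_that("single-SNP scan matches a brute-force regression oracle", {
  set.seed(33)
  p <- random_panel(n = 30, m = 4, seed = 33, miss = 0.05, het = 0)
  acc <- p$accession_ids
  pcs <- matrix(rnorm(60), 30, 2, dimnames = list(acc, c("PC1", "PC2")))
  s <- structure(list(pc_coords = pcs), class = "structure_result")
  tt <- data.frame(accession_id = acc, Glu = rnorm(30, 2, 0.3))
  class(tt) <- c("trait_table", "data.frame")
  idx <- list(G1 = 1:4)
  res <- run_snp_scan(p, idx, tt, s, scan_config(Q = 2),
                      pairs = data.frame(gene_id = "G1", trait = "Glu"))
  expect_equal(nrow(res), 4L)
  for (j in which(!res$skipped)) {
    dose <- p$calls[, j]
    ok <- !is.na(dose)
    fit <- lm(tt$Glu[ok] ~ pcs[ok, 1] + pcs[ok, 2] + dose[ok])
    co <- summary(fit)$coefficients
    expect_equal(res$beta[j], co[4, 1], tolerance = 1e-10)
    expect_equal(res$p_value[j], co[4, 4], tolerance = 1e-10)
  }
  ## constant dosage column is skipped
  p2 <- p
  p2$calls[, 2] <- 0L
  res2 <- run_snp_scan(p2, idx, tt, s, scan_config(Q = 2),
                       pairs = data.frame(gene_id = "G1", trait = "Glu"))
  expect_true(res2$skipped[2])
})

test_that("key variant selection equals argmin with positional tie-break", {
  base <- data.frame(
    snp_id = c("s1", "s2"), gene_id = "G1", trait = "Glu", chrom = "chr1",
    pos = c(100L, 200L), ref = "A", alt = "G", beta = 1,
    p_value = c(1e-6, 1e-6), skipped = FALSE, is_key_variant = FALSE,
    stringsAsFactors = FALSE)
  out <- key_variant_per_gene(base, "G1", "Glu")
  expect_identical(out$snp_id[out$is_key_variant], "s1")
  ## gene with one SNP: that SNP is key
  out1 <- key_variant_per_gene(base[2, ], "G1", "Glu")
  expect_true(out1$is_key_variant)
  ## random p-vector equals argmin oracle
  set.seed(40)
  for (rep in 1:10) {
    k <- 8
    df <- data.frame(snp_id = paste0("s", 1:k), gene_id = "G", trait = "t",
                     chrom = "chr1", pos = sample.int(1e5, k), ref = "A",
                     alt = "G", beta = 0, p_value = runif(k),
                     skipped = FALSE, is_key_variant = FALSE,
                     stringsAsFactors = FALSE)
    out <- key_variant_per_gene(df, "G", "t")
    expect_equal(which(out$is_key_variant), which.min(df$p_value))
  }
  expect_warning(key_variant_per_gene(base[0, ], "G1", "Glu"), "no scored")
})

test_that("gwha scan finds a planted causal gene among nulls", {
  cfg <- sim_config(n_accessions = 164, n_genes = 40,
                    snps_per_gene = c(2, 12), structure_effect = 0.2,
                    causal_genes = list(list(gene = 10, trait = "Cys",
                                             fve = 0.3)),
                    seed = 55)
  sim <- simulate_panel(cfg)
  traits <- simulate_traits(sim$panel, sim$truth, cfg)
  panel <- filter_panel(sim$panel, compute_snp_qc(sim$panel))
  idx <- assign_snps_to_genes(panel, sim$genes)
  haps <- build_all_haplotypes(panel, idx, 5)
  s <- pca_structure(dosage_matrix(panel), 3)
  res <- run_gwha_scan(panel, idx, haps, traits, s, scan_config(Q = 2),
                       genes = sim$genes)
  cys <- res[res$trait == "Cys", ]
  expect_equal(cys$gene_id[which.min(cys$p_value)], "G0010")
  ## deterministic ordering: (chrom, gene start, trait)
  expect_false(is.unsorted(order(match(res$chrom, unique(res$chrom)),
                                 res$gene_start, res$trait)))
  ## single gene x single trait -> one record
  one <- run_gwha_scan(panel, idx[1], haps["G0001"],
                       tt <- traits[c("accession_id", "Glu")],
                       s, scan_config(Q = 2), genes = sim$genes)
  expect_equal(nrow(one), 1L)
})

test_that("manhattan/QQ export follows the documented definitions", {
  res <- data.frame(gene_id = paste0("G", 1:3), trait = "Glu",
                    chrom = "chr1", p_value = c(0.5, 0.01, 0.2),
                    gene_mid = c(150, 2500, 9000),
                    stringsAsFactors = FALSE)
  pre <- file.path(withr::local_tempdir(), "plot")
  export_manhattan_qq(res, pre)
  man <- read.delim(paste0(pre, "_manhattan.tsv"))
  expect_equal(nrow(man), 3L)
  expect_equal(man$neg_log10_p, -log10(res$p_value))
  expect_equal(man$position, res$gene_mid)
  qq <- read.delim(paste0(pre, "_qq.tsv"))
  expect_equal(qq$expected, -log10((1:3 - 0.5) / 3))
  expect_equal(qq$observed, -log10(sort(res$p_value)))
})
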