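test_that("cis windows are closed at exactly 250 kb", {
  set.seed(30)
  n <- 100
  C <- make_covariates(n)
  x <- rbinom(n, 2, 0.3) + 0
  G <- make_genotypes(matrix(x, n, 1, dimnames = list(C$data$sample_id, "v1")),
                      chrom = "1", pos = 1e6)
  ## gene intervals at distances exactly 250000 and 250001 from the variant
  E <- trait_matrix(matrix(rnorm(n * 3), n, 3,
                           dimnames = list(C$data$sample_id,
                                           c("at", "beyond", "inside"))),
                    data.frame(id = c("at", "beyond", "inside"), chrom = "1",
                               start = c(1e6 + 250000, 1e6 + 250001, 9.9e5),
                               end = c(1e6 + 260000, 1e6 + 260001, 1.1e6),
                               stringsAsFactors = FALSE),
                    scale_tag = "expression")
  res <- cis_eqtl("v1", G, E, C)
  expect_setequal(res$feature_id, c("at", "inside"))
  ## no genes in window: empty result with a warning
  E2 <- trait_matrix(E$values[, 1, drop = FALSE],
                     transform(E$features[1, ], chrom = "2"),
                     scale_tag = "expression")
  expect_warning(out <- cis_eqtl("v1", G, E2, C), "no genes")
  expect_identical(nrow(out), 0L)
})

test_that("planted cis-eQTL effects are recovered with Bonferroni control", {
  cfg <- sim_config(n_females = 800, n_males = 0, n_variants = 10, n_x_cpgs = 5,
                    n_autosomal_cpgs = 1, n_genes = 8, seed = 33,
                    planted_loci = list(planted_locus(
                      2, maf = 0.3, cis_gene_index = 1, cis_effect = -0.3)))
  G <- simulate_genotypes(cfg); C <- simulate_covariates(cfg)
  truth <- ground_truth(cfg, G)
  E <- simulate_expression(G, C, truth, cfg)
  res <- cis_eqtl("var00002", G, int_transform(E, C), C)
  hit <- res[res$feature_id == "gene001", ]
  expect_true(hit$significant)
  expect_lt(hit$beta, 0)
})

test_that("trans mapping excludes the 5 Mb neighbourhood but keeps other chromosomes", {
  set.seed(34)
  n <- 150
  C <- make_covariates(n)
  x <- rbinom(n, 2, 0.3) + 0
  G <- make_genotypes(matrix(x, n, 1, dimnames = list(C$data$sample_id, "v1")),
                      chrom = "1", pos = 1e7)
  V <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(C$data$sample_id, c("near", "far", "other")))
  Y <- trait_matrix(V, data.frame(id = c("near", "far", "other"),
                                  chrom = c("1", "1", "2"),
                                  start = c(1.4e7, 1.6e7, 100),
                                  end = c(1.4e7, 1.6e7, 100) + 1,
                                  stringsAsFactors = FALSE),
                    scale_tag = "normalized")
  res <- trans_meqtl("v1", G, Y, C)
  expect_setequal(res$feature_id, c("far", "other"))  # 4 Mb CpG excluded
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("the strongest X cis-meQTL is selected with a positional tie-break", {
  set.seed(35)
  n <- 200
  C <- make_covariates(n)
  xa <- rbinom(n, 2, 0.3) + 0
  dos <- cbind(xa, xa, rbinom(n, 2, 0.3))  # two identical candidates + noise
  dimnames(dos) <- list(C$data$sample_id, c("xv1", "xv2", "xv3"))
  G_x <- make_genotypes(dos + 0, chrom = "X", pos = c(2e6, 1e6, 1.2e6))
  V <- matrix(rnorm(n), n, 1, dimnames = list(C$data$sample_id, "cg1"))
  V[, 1] <- V[, 1] + 0.8 * xa
  Y <- trait_matrix(V, data.frame(id = "cg1", chrom = "X", start = 1.1e6,
                                  end = 1.1e6 + 1, stringsAsFactors = FALSE),
                    scale_tag = "normalized")
  res <- cis_meqtl_x("cg1", G_x, Y, C)
  expect_identical(res$cis_snp_id, "xv2")  # tie broken toward lower position
  ## CpG with no variant in the window: none selected
  Y2 <- trait_matrix(V, transform(Y$features, start = 9e7, end = 9e7 + 1),
                     scale_tag = "normalized")
  expect_true(is.na(cis_meqtl_x("cg1", G_x, Y2, C)$cis_snp_id))
})

test_that("cis-SNP adjustment leaves unmediated trans effects and removes mediated ones", {
  set.seed(36)
  n <- 500
  C <- make_covariates(n)
  x_auto <- rbinom(n, 2, 0.3) + 0
  x_cis <- rbinom(n, 2, 0.3) + 0
  G <- make_genotypes(matrix(x_auto, n, 1,
                             dimnames = list(C$data$sample_id, "vA")),
                      chrom = "1", pos = 1e6)
  G_x <- make_genotypes(matrix(x_cis, n, 1,
                               dimnames = list(C$data$sample_id, "vX")),
                        chrom = "X", pos = 5e6)
  ## independent effects
  y1 <- 0.4 * x_auto + 0.4 * x_cis + rnorm(n)
  ## fully mediated: the autosomal dosage only matters through the cis SNP
  ## (association induced by sharing the cis-driven component)
  y2 <- 0.8 * x_cis + rnorm(n, 0, 0.1)
  V <- cbind(ind = y1, med = y2)
  rownames(V) <- C$data$sample_id
  Y <- trait_matrix(V, data.frame(id = c("ind", "med"), chrom = "X",
                                  start = c(5e6, 5e6), end = c(5e6, 5e6) + 1,
                                  stringsAsFactors = FALSE),
                    scale_tag = "normalized")
  r1 <- adjusted_trans_effect("vA", "ind", "vX", G, G_x, Y, C)
  expect_lt(abs(r1$beta_adjusted - r1$beta_unadjusted), 0.1)
  ## no cis SNP: adjusted equals unadjusted exactly
  r0 <- adjusted_trans_effect("vA", "ind", NA, G, G_x, Y, C)
  expect_identical(r0$beta_adjusted, r0$beta_unadjusted)
  ## collinear "cis" SNP is a data-corruption error
  G_bad <- make_genotypes(matrix(x_auto, n, 1,
                                 dimnames = list(C$data$sample_id, "vX")),
                          chrom = "X", pos = 5e6)
  expect_error(adjusted_trans_effect("vA", "ind", "vX", G, G_bad, Y, C),
               "collinear")
})

test_that("CpG-to-expression coupling is windowed and detects shared drivers", {
  set.seed(37)
  n <- 400
  C <- make_covariates(n)
  x <- rbinom(n, 2, 0.3) + 0
  meth <- pmin(pmax(0.3 - 0.03 * x + rnorm(n, 0, 0.02), 0), 1)
  expr <- 5 - 0.3 * x + rnorm(n, 0, 0.5)
  Y <- trait_matrix(matrix(meth, n, 1, dimnames = list(C$data$sample_id, "cg1")),
                    data.frame(id = "cg1", chrom = "X", start = 1e6,
                               end = 1e6 + 1, stringsAsFactors = FALSE),
                    scale_tag = "beta")
  E <- trait_matrix(matrix(expr, n, 1, dimnames = list(C$data$sample_id, "g1")),
                    data.frame(id = "g1", chrom = "X", start = 1.1e6,
                               end = 1.15e6, stringsAsFactors = FALSE),
                    scale_tag = "expression")
  res <- cpg_expression_assoc("cg1", Y, E, C)
  expect_true(res$significant)
  expect_gt(res$beta, 0)  # hypomethylation allele lowers expression jointly
  ## permuted expression: association gone
  Eperm <- E; Eperm$values[, 1] <- sample(E$values[, 1])
  expect_false(cpg_expression_assoc("cg1", Y, Eperm, C)$significant)
  ## CpG with no gene in the window
  Yfar <- Y; Yfar$features$start <- 9e7; Yfar$features$end <- 9e7 + 1
  expect_warning(out <- cpg_expression_assoc("cg1", Yfar, E, C), "no genes")
  expect_identical(nrow(out), 0L)
})

test_that("window specifications validate their ordering", {
  expect_error(window_spec(cis_window = 6e6), "smaller than")
  expect_error(window_spec(proxy_window = -1), "positive")
})
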