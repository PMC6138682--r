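test_that("genotypes follow Hardy-Weinberg proportions at the configured MAF", {
  cfg <- sim_config(n_females = 10000, n_males = 0, n_cohorts = 1,
                    n_variants = 5, n_x_cpgs = 2, n_autosomal_cpgs = 1,
                    n_genes = 1, maf_range = c(0.3, 0.3), seed = 42)
  G <- simulate_genotypes(cfg)
  n <- nrow(G$dosages)
  exp_p <- c(0.49, 0.42, 0.09)  # p^2, 2pq, q^2 at q = 0.3
  for (j in seq_len(ncol(G$dosages))) {
    obs <- tabulate(G$dosages[, j] + 1, 3) / n
    se <- sqrt(exp_p * (1 - exp_p) / n)
    expect_true(all(abs(obs - exp_p) < 3 * se),
                info = sprintf("variant %d proportions %s", j,
                               paste(round(obs, 3), collapse = ",")))
  }
  ## symmetric MAF 0.5: empirical allele frequency near 0.5
  cfg5 <- sim_config(n_females = 10000, n_males = 0, n_variants = 5,
                     n_x_cpgs = 2, n_autosomal_cpgs = 1, n_genes = 1,
                     maf_range = c(0.5, 0.5), seed = 7)
  G5 <- simulate_genotypes(cfg5)
  af <- colMeans(G5$dosages) / 2
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.5 * 0.5 / (2 * n))))
})

test_that("simulation is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_females = 100, n_males = 50, n_variants = 30,
                    n_x_cpgs = 30, n_autosomal_cpgs = 10, n_genes = 5,
                    n_x_variants = 5, seed = 11,
                    planted_loci = list(planted_locus(3, target_cpg_indices = 1:5,
                                                      per_allele_effect_beta = -0.02)))
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$G$dosages, b$G$dosages)
  expect_identical(a$Y_x$values, b$Y_x$values)
  expect_identical(a$E$values, b$E$values)
  expect_identical(a$C$data, b$C$data)
  expect_identical(a$truth$annotation_assignment, b$truth$annotation_assignment)
})

test_that("simulated variants pass the exact HWE test at QC rates", {
  cfg <- sim_config(n_females = 5000, n_males = 0, n_variants = 300,
                    n_x_cpgs = 2, n_autosomal_cpgs = 1, n_genes = 1, seed = 5)
  G <- simulate_genotypes(cfg)
  expect_gte(mean(G$variants$hwe_p > 1e-4), 0.99)
})

test_that("covariates have the requested cohort, latent and positivity structure", {
  cfg <- sim_config(n_females = 120, n_males = 60, n_cohorts = 6,
                    n_variants = 5, n_x_cpgs = 5, n_autosomal_cpgs = 1,
                    n_genes = 1, seed = 2)
  C <- simulate_covariates(cfg)
  expect_length(unique(C$data$cohort), 6L)
  cells <- as.matrix(C$data[c("lymphocytes", "neutrophils", "monocytes",
                              "eosinophils", "basophils", "rbc")])
  expect_true(all(cells > 0))
  cfg0 <- sim_config(n_females = 50, n_males = 0, n_variants = 5, n_x_cpgs = 5,
                     n_autosomal_cpgs = 1, n_genes = 1, n_latent_factors = 0,
                     seed = 2)
  expect_identical(ncol(simulate_covariates(cfg0)$latent), 0L)
})

test_that("planted methylation effects are recovered at the configured size and sex", {
  cfg <- sim_config(n_females = 2000, n_males = 1500, n_variants = 10,
                    n_x_cpgs = 20, n_autosomal_cpgs = 1, n_genes = 1, seed = 21,
                    planted_loci = list(planted_locus(
                      2, maf = 0.4, target_cpg_indices = 1:3,
                      per_allele_effect_beta = -0.016)))
  G <- simulate_genotypes(cfg); C <- simulate_covariates(cfg)
  truth <- ground_truth(cfg, G)
  Y <- simulate_methylation(G, C, truth, cfg, "X")
  fem <- C$data$sex == "female"
  x <- G$dosages[, 2]
  for (j in 1:3) {
    fit <- lm(Y$values[fem, j] ~ x[fem])
    est <- coef(summary(fit))[2, ]
    expect_lt(abs(est["Estimate"] - (-0.016)), 3 * est["Std. Error"])
    ## female-specific: no dosage effect in males
    fitm <- lm(Y$values[!fem, j] ~ x[!fem])
    estm <- coef(summary(fitm))[2, ]
    expect_lt(abs(estm["Estimate"]), 3 * estm["Std. Error"])
  }
  expect_true(all(Y$values >= 0 & Y$values <= 1))
})

test_that("with all noise and confounding off, methylation equals the baselines", {
  cfg <- sim_config(n_females = 30, n_males = 0, n_variants = 5, n_x_cpgs = 8,
                    n_autosomal_cpgs = 1, n_genes = 1, n_latent_factors = 0,
                    noise_sd = 0, cell_effect_sd = 0, latent_effect_sd = 0,
                    cohort_effect_sd = 0, seed = 3)
  G <- simulate_genotypes(cfg); C <- simulate_covariates(cfg)
  truth <- ground_truth(cfg, G)
  Y <- simulate_methylation(G, C, truth, cfg, "X")
  expect_equal(unname(Y$values), matrix(rep(truth$x_baselines, each = 30), 30),
               tolerance = 1e-15)
})

test_that("planted cis expression effects are recovered; null genes are flat", {
  cfg <- sim_config(n_females = 1000, n_males = 0, n_variants = 10,
                    n_x_cpgs = 5, n_autosomal_cpgs = 1, n_genes = 4, seed = 31,
                    planted_loci = list(planted_locus(
                      2, maf = 0.3, cis_gene_index = 1, cis_effect = -0.13)))
  G <- simulate_genotypes(cfg); C <- simulate_covariates(cfg)
  truth <- ground_truth(cfg, G)
  E <- simulate_expression(G, C, truth, cfg)
  x <- G$dosages[, 2]
  est <- coef(summary(lm(E$values[, 1] ~ x)))[2, ]
  expect_lt(abs(est["Estimate"] - (-0.13)), 3 * est["Std. Error"])
  est0 <- coef(summary(lm(E$values[, 2] ~ x)))[2, ]
  expect_lt(abs(est0["Estimate"]), 3 * est0["Std. Error"])
})

test_that("annotation tracks round-trip through BED and respect enrichment_factor = 1", {
  feat <- data.frame(id = sprintf("cg%05d", 1:2000), chrom = "X",
                     start = sort(sample.int(1.4e8, 2000)) + 1e5,
                     stringsAsFactors = FALSE)
  sa <- simulate_annotations(feat, target_cpg_ids = feat$id[1:50],
                             enrichment_factor = 1, seed = 9)
  ## no enrichment: target and background CGI rates should not differ
  a <- sa$assignment
  tgt <- a$cgi_class[1:50] == "island"
  bg <- a$cgi_class[-(1:50)] == "island"
  expect_gt(fisher.test(table(factor(c(tgt, bg), c(FALSE, TRUE)),
                              rep(c("t", "b"), c(50, 1950))))$p.value, 0.001)
  ## write + re-read: identical interval sets
  dir <- withr::local_tempdir()
  write_annotations(sa$annotations, dir)
  back <- read_annotations(c(CGI = file.path(dir, "CGI.bed"),
                             H3K27me3 = file.path(dir, "H3K27me3.bed")),
                           file.path(dir, "tss.tsv"))
  for (nm in names(sa$annotations$tracks)) {
    expect_identical(GenomicRanges::start(back$tracks[[nm]]),
                     GenomicRanges::start(sa$annotations$tracks[[nm]]))
    expect_identical(GenomicRanges::end(back$tracks[[nm]]),
                     GenomicRanges::end(sa$annotations$tracks[[nm]]))
  }
  expect_equal(back$tss[c("chrom", "pos", "gene", "class")],
               sa$annotations$tss[c("chrom", "pos", "gene", "class")])
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(baseline_beta_range = c(0.1, 1)), "baseline_beta_range")
  expect_error(sim_config(n_variants = 5, planted_loci = list(
    planted_locus(10, target_cpg_indices = 1))), "variant_index")
  expect_error(sim_config(n_x_cpgs = 10, planted_loci = list(
    planted_locus(1, target_cpg_indices = 11))), "X CpG range")
  expect_error(planted_locus(1, direction_consistency = 0.4),
               "direction_consistency")
})
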