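test_that("wald_assoc matches the normal-equations oracle on small instances", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 15
    C <- make_covariates(n, seed = rep)
    x <- rbinom(n, 2, 0.4) + 0
    while (sd(x) == 0) x <- rbinom(n, 2, 0.4) + 0
    Y <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(C$data$sample_id, paste0("cg", 1:4)))
    a <- wald_assoc(x, make_traits(Y), C)
    X <- cbind(build_design(C), x)
    for (j in 1:4) {
      o <- ols_oracle(Y[, j], X)
      expect_equal(a$beta[j], unname(o$beta), tolerance = 1e-10)
      expect_equal(a$se[j], unname(o$se), tolerance = 1e-10)
      expect_equal(a$t_stat[j], unname(o$t), tolerance = 1e-10)
      expect_equal(a$p[j], unname(o$p), tolerance = 1e-10)
      expect_identical(a$df[j], as.integer(o$df))
    }
  }
  ## degenerate inputs
  C <- make_covariates(12)
  Y <- make_traits(matrix(rnorm(24), 12, 2,
                          dimnames = list(C$data$sample_id, c("a", "b"))))
  expect_error(wald_assoc(rep(1, 12), Y, C), "zero-variance")
  x <- rbinom(12, 2, 0.5) + 0
  expect_error(wald_assoc(x, Y, C, extra = list(xcopy = x)), "collinear")
})

test_that("Simes combination reproduces hand-computed values and its bounds", {
  expect_equal(simes_combine(c(0.01, 0.02, 0.9)), 0.03)
  expect_equal(simes_combine(rep(0.37, 6)), 0.37)
  expect_equal(simes_combine(0.123), 0.123)
  expect_error(simes_combine(numeric(0)), "at least one")
  expect_error(simes_combine(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(simes_combine(c(0.1, 1.1)), "\\(0, 1\\]")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    s <- simes_combine(p)
    expect_equal(s, simes_oracle(p), tolerance = 1e-12)
    expect_gte(s, min(p))
    expect_lte(s, min(1, length(p) * min(p)))
  }
})

test_that("the exact sign test returns the documented worked values", {
  expect_identical(direction_consistency_test(k = 5, n = 10), 1)
  expect_equal(direction_consistency_test(k = 10, n = 10), 2 * (1 / 2^10),
               tolerance = 1e-15)
  expect_equal(direction_consistency_test(k = 56, n = 57), 2 * (58 / 2^57),
               tolerance = 1e-12)
  expect_equal(direction_consistency_test(c(1, 1, -1, 1)),
               direction_consistency_test(c(-1, -1, 1, -1)))  # symmetry
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:40, 1); k <- sample(0:n, 1)
    expect_equal(direction_consistency_test(k = k, n = n), sign_oracle(k, n),
                 tolerance = 1e-12)
  }
})

test_that("global scan flags only truly associated variants", {
  set.seed(13)
  n <- 300
  C <- make_covariates(n)
  G <- make_genotypes(matrix(rbinom(n * 30, 2, 0.3) + 0, n, 30,
                             dimnames = list(C$data$sample_id, NULL)))
  V <- matrix(rnorm(n * 40), n, 40, dimnames = list(C$data$sample_id, NULL))
  ## plant one variant affecting 10 CpGs
  V[, 1:10] <- V[, 1:10] + 0.5 * G$dosages[, 7]
  Y <- make_traits(V)
  sc <- global_scan(G, Y, C)
  expect_identical(sc$significant, "v0007")
  expect_identical(sc$records$n_tests, rep(40L, 30))
  ## Simes minimum is attained at an affected CpG
  expect_true(sc$records$argmin_feature[7] %in% sprintf("cg%04d", 1:10))
  ## alpha = 1: every variant is significant
  expect_length(global_scan(G, Y, C, alpha = 1)$significant, 30L)
})

test_that("conditional discovery reports each locus once, in strength order", {
  set.seed(14)
  n <- 500
  C <- make_covariates(n)
  dos <- matrix(rbinom(n * 20, 2, 0.3) + 0, n, 20)
  ## v3 and v4 are LD proxies (same block); v10 an independent weaker locus
  dos[, 4] <- ifelse(runif(n) < 0.95, dos[, 3], rbinom(n, 2, 0.3))
  G <- make_genotypes(dos, chrom = rep(c("1", "2"), each = 10),
                      pos = rep(seq_len(10) * 1e5, 2))
  V <- matrix(rnorm(n * 50), n, 50, dimnames = list(C$data$sample_id, NULL))
  V[, 1:15] <- V[, 1:15] + 0.6 * dos[, 3]
  V[, 31:40] <- V[, 31:40] + 0.5 * dos[, 10]
  loci <- conditional_scan(G, make_traits(V), C)
  expect_identical(loci$sentinel_variant_id, c("v0003", "v0010"))
  expect_identical(loci$conditioned_on, c("", "v0003"))
  expect_true(all(diff(loci$iteration) == 1))
  ## null data: no loci
  Vnull <- matrix(rnorm(n * 30), n, 30, dimnames = list(C$data$sample_id, NULL))
  expect_identical(nrow(conditional_scan(G, make_traits(Vnull), C)), 0L)
})

test_that("male validation applies the overall-P exclusion rule with proxies", {
  set.seed(15)
  n_f <- 400; n_m <- 300
  sex <- rep(c("female", "male"), c(n_f, n_m))
  C <- make_covariates(n_f + n_m, sex = sex)
  dos <- matrix(rbinom((n_f + n_m) * 10, 2, 0.3) + 0, n_f + n_m, 10)
  dos[, 2] <- ifelse(runif(n_f + n_m) < 0.95, dos[, 1], rbinom(n_f + n_m, 2, 0.3))
  G <- make_genotypes(dos, pos = c(1e6, 1.5e6, 3e6 + seq_len(8) * 1e6))
  V <- matrix(rnorm((n_f + n_m) * 30), n_f + n_m, 30,
              dimnames = list(C$data$sample_id, NULL))
  fem <- sex == "female"
  ## female-specific signal at v1
  V[fem, 1:10] <- V[fem, 1:10] + 0.5 * dos[fem, 1]
  ids_f <- C$data$sample_id[fem]; ids_m <- C$data$sample_id[!fem]
  G_f <- xscan:::subset_samples(G, ids_f); G_m <- xscan:::subset_samples(G, ids_m)
  C_f <- xscan:::subset_samples(C, ids_f); C_m <- xscan:::subset_samples(C, ids_m)
  Y <- make_traits(V)
  Y_f <- xscan:::subset_samples(Y, ids_f); Y_m <- xscan:::subset_samples(Y, ids_m)
  loci <- conditional_scan(G_f, Y_f, C_f)
  expect_identical(loci$sentinel_variant_id, "v0001")
  mv <- male_validation(loci, G_m, Y_m, C_m)
  expect_identical(mv$n_proxies, 1L)  # v2 is an r2 >= 0.8 proxy within 1 Mb
  expect_true(mv$female_specific)
  expect_false(mv$replicates_in_males)
  expect_error(male_validation(data.frame(sentinel_variant_id = "nope"),
                               G_m, Y_m, C_m), "absent")
})

test_that("interaction test requires both sexes and finds female-only effects", {
  set.seed(16)
  n <- 600
  sex <- rep(c("female", "male"), each = n / 2)
  C <- make_covariates(n, sex = sex)
  x <- rbinom(n, 2, 0.3) + 0
  V <- matrix(rnorm(n * 20), n, 20, dimnames = list(C$data$sample_id, NULL))
  V[sex == "female", 1:8] <- V[sex == "female", 1:8] + 0.5 * x[sex == "female"]
  it <- interaction_test(x, make_traits(V), C)
  expect_lt(it$overall_p, 5.9e-4)
  ## equal-in-both-sexes effect: interaction is null
  V2 <- matrix(rnorm(n * 20), n, 20, dimnames = list(C$data$sample_id, NULL))
  V2[, 1:8] <- V2[, 1:8] + 0.5 * x
  expect_gt(interaction_test(x, make_traits(V2), C)$overall_p, 1e-3)
  C_f <- xscan:::subset_samples(C, C$data$sample_id[sex == "female"])
  expect_error(interaction_test(x[sex == "female"],
                                xscan:::subset_samples(make_traits(V),
                                                       C_f$data$sample_id),
                                C_f), "both sexes")
})

test_that("per-CpG effect lists apply BH step-up and report raw-scale betas", {
  set.seed(17)
  n <- 400
  C <- make_covariates(n)
  x <- rbinom(n, 2, 0.3) + 0
  base <- runif(30, 0.2, 0.5)
  V <- matrix(rep(base, each = n), n, 30) + matrix(rnorm(n * 30, 0, 0.02), n, 30)
  V[, 1:10] <- V[, 1:10] - 0.015 * x
  V <- pmin(pmax(V, 0), 1)
  dimnames(V) <- list(C$data$sample_id, sprintf("cg%02d", 1:30))
  Yb <- make_traits(V, scale_tag = "beta")
  Yn <- int_transform(Yb, C)
  pe <- per_cpg_effects(x, Yn, Yb, C)
  truth_ids <- sprintf("cg%02d", 1:10)
  ## every affected CpG is recovered; BH admits at most its FDR share of nulls
  expect_true(all(truth_ids %in% pe$significant$feature_id))
  expect_lte(nrow(pe$significant), 12L)
  true_rows <- pe$significant[pe$significant$feature_id %in% truth_ids, ]
  expect_lt(abs(mean(true_rows$beta_raw) - (-0.015)), 0.004)
  expect_true(all(true_rows$beta_raw < 0))
  expect_lt(pe$direction$sign_test_p, 0.05)
  ## all-null p-vector: empty significant set
  pe0 <- per_cpg_effects(rbinom(n, 2, 0.5) + 0, Yn, Yb, C)
  ## (a fresh random dosage is null for every CpG)
  expect_lte(nrow(pe0$significant), 1L)
})
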