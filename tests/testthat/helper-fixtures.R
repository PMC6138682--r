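## Shared fixtures and independent oracles. Oracles are deliberately
## naive (explicit normal equations, enumeration, direct formulas) and
## never call the package code paths they check.

make_covariates <- function(n, sex = rep("female", n),
                            cohort = rep("c1", n), batch = rep("b1", n),
                            latent = NULL, seed = 1) {
  set.seed(seed)
  covariate_bundle(data.frame(
    sample_id = sprintf("s%04d", seq_len(n)), sex = sex,
    age = sample(20:70, n, replace = TRUE), cohort = cohort,
    lymphocytes = rlnorm(n, 0.7, 0.3), neutrophils = rlnorm(n, 1.3, 0.3),
    monocytes = rlnorm(n, -0.7, 0.3), eosinophils = rlnorm(n, -1.6, 0.3),
    basophils = rlnorm(n, -3, 0.3), rbc = rlnorm(n, 1.5, 0.3),
    batch = batch, stringsAsFactors = FALSE), latent = latent)
}

make_traits <- function(V, chrom = "X", pos = NULL, scale_tag = "normalized") {
  if (is.null(pos)) pos <- seq_len(ncol(V)) * 1000L
  if (is.null(colnames(V))) colnames(V) <- sprintf("cg%04d", seq_len(ncol(V)))
  trait_matrix(V, data.frame(id = colnames(V), chrom = chrom, start = pos,
                             end = pos + 1L, stringsAsFactors = FALSE),
               scale_tag = scale_tag)
}

make_genotypes <- function(dos, chrom = NULL, pos = NULL) {
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("s%04d", seq_len(nrow(dos)))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("v%04d", seq_len(ncol(dos)))
  if (is.null(chrom)) chrom <- rep("1", ncol(dos))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1e6
  genotype_matrix(dos, data.frame(id = colnames(dos), chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE))
}

## --- independent oracles -----------------------------------------------

## OLS via explicit normal equations: coefficient, se, t of the LAST column
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  bh <- solve(XtX, crossprod(X, y))
  res <- y - X %*% bh
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  covb <- s2 * solve(XtX)
  k <- ncol(X)
  t <- bh[k] / sqrt(covb[k, k])
  list(beta = bh[k], se = sqrt(covb[k, k]), t = t, df = df,
       p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

simes_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  best <- Inf
  for (j in seq_len(m)) best <- min(best, m * ps[j] / j)
  min(1, best)
}

bh_oracle <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (j in m:1) if (ps[j] <= fdr * j / m) { k <- j; break }
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

## two-sided Fisher exact p by enumerating all tables with fixed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  supp <- max(0, k - n):min(k, m)
  pr <- dhyper(supp, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## exact two-sided sign test by direct binomial tail summation
sign_oracle <- function(k, n) {
  pmf <- choose(n, 0:n) / 2^n
  lower <- sum(pmf[1:(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

stouffer_oracle <- function(t, w) {
  ok <- !is.na(t)
  sum(w[ok] * t[ok]) / sqrt(sum(w[ok]^2))
}

## --- the reference power-study conditions (one planted female-specific
## locus: MAF 0.3, -0.015 beta per allele at 50 of 500 X CpGs) ----------

power_config <- function(seed, n_variants = 50, effect = -0.015,
                         targets = 1:50, extra_loci = list(),
                         n_females = 1000, n_males = 600) {
  sim_config(n_females = n_females, n_males = n_males,
             n_variants = n_variants, n_x_cpgs = 500,
             n_autosomal_cpgs = 1, n_genes = 1, n_x_variants = 1,
             seed = seed,
             planted_loci = c(list(
               planted_locus(10L, maf = 0.3, target_cpg_indices = targets,
                             per_allele_effect_beta = effect)),
               extra_loci))
}

## simulate + preprocess the discovery strata for a power config
power_study <- function(cfg) {
  G <- simulate_genotypes(cfg)
  C <- simulate_covariates(cfg)
  truth <- ground_truth(cfg, G)
  Y <- simulate_methylation(G, C, truth, cfg, which = "X")
  fem <- C$data$sample_id[C$data$sex == "female"]
  mal <- C$data$sample_id[C$data$sex == "male"]
  prep <- function(ids) {
    Gs <- xscan:::subset_samples(G, ids)
    Cs <- xscan:::subset_samples(C, ids)
    Ys <- xscan:::subset_samples(Y, ids)
    Yn <- int_transform(Ys, Cs)
    lf <- estimate_latent_factors(residualize(Yn, Cs, include_latent = FALSE))
    list(G = Gs, Y = Yn, Y_beta = Ys, C = set_latent_factors(Cs, lf))
  }
  out <- list(G = G, C = C, Y = Y, truth = truth, female = prep(fem))
  if (length(mal)) out$male <- prep(mal)
  ## combined stratum for the interaction test
  Yn_all <- int_transform(Y, C)
  lf_all <- estimate_latent_factors(residualize(Yn_all, C, include_latent = FALSE))
  out$combined <- list(G = G, Y = Yn_all, C = set_latent_factors(C, lf_all))
  out
}
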