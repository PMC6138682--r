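## Mass-univariate OLS association core. By the Frisch-Waugh-Lovell
## theorem the Wald t for the genotype coefficient in the full model
## [intercept, x, M, U] equals the simple-regression t between the
## covariate-residualized x and y, with df = n - ncol(design) - 1; this
## lets a whole variant panel be tested against a whole trait matrix
## with two QR residualizations and one cross-product.

assoc_core <- function(X, Y, design, x_tol = 1e-10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(design)
  if (nrow(X) != n || nrow(Y) != n) stopf("sample dimension mismatch in association")
  if (anyNA(X)) stopf("genotype matrix contains missing dosages; impute first")
  df <- n - ncol(design) - 1L
  if (df < 1L) stopf("not enough samples for the design (df = %d)", df)
  qd <- qr(design)
  Xr <- qr.resid(qd, X)
  Yr <- qr.resid(qd, Y)
  sx2 <- colSums(Xr^2)
  sy2 <- colSums(Yr^2)
  dropped <- sx2 < x_tol * pmax(colSums(X^2), 1)
  sx2[dropped] <- NA_real_
  Cm <- crossprod(Xr, Yr)            # v x m
  beta <- Cm / sx2
  rss <- matrix(sy2, nrow(Cm), ncol(Cm), byrow = TRUE) - Cm^2 / sx2
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / sx2)
  t <- beta / se
  p <- t_pvalue(t, df)
  p[se == 0] <- 0  # perfect fit limit
  list(beta = beta, se = se, t = t, p = p, df = df, dropped = dropped)
}

#' Per-CpG Wald association of one variant
#'
#' Fits, per trait feature, the linear model
#' `y = beta * x + gamma M (+ delta U)` by OLS and returns the Wald test
#' of the genotype coefficient against zero (two-sided p from the t
#' distribution with `n - n_columns` residual degrees of freedom).
#'
#' @param x Dosage vector (named by sample, or aligned with `Y`).
#' @param Y A [trait_matrix()] or numeric matrix of traits.
#' @param C A [covariate_bundle()].
#' @param include_latent Include latent factor covariates.
#' @param extra Extra design columns (e.g. sentinel dosages).
#' @return Data frame of class `AssocStat`: `feature_id`, `beta`, `se`,
#'   `t_stat`, `df`, `p`.
#' @export
wald_assoc <- function(x, Y, C, include_latent = TRUE, extra = NULL) {
  V <- if (inherits(Y, "TraitMatrix")) Y$values else Y
  if (!identical(rownames(V), C$data$sample_id))
    stopf("trait and covariate samples do not match")
  if (length(x) != nrow(V)) stopf("dosage vector length does not match samples")
  if (stats::sd(x) == 0) stopf("zero-variance genotype vector")
  design <- build_design(C, include_latent = include_latent, extra = extra)
  res <- assoc_core(matrix(x, ncol = 1L), V, design)
  if (res$dropped[1L])
    stopf("genotype vector is collinear with the covariate design")
  out <- data.frame(feature_id = colnames(V), beta = res$beta[1L, ],
                    se = res$se[1L, ], t_stat = res$t[1L, ], df = res$df,
                    p = res$p[1L, ], stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("AssocStat", class(out))
  out
}
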