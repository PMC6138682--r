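## Variant QC, within-cohort rank-based inverse-normal transformation,
## covariate residualization, and latent-factor confounder estimation
## (PCA on residuals with the eigenvalue-difference rule).

#' Variant QC thresholds
#'
#' Defaults are the standard post-imputation filter: info score >= 0.5,
#' exact HWE P >= 1e-4, call rate >= 95%, MAF >= 1%.
#'
#' @param info_min,hwe_p_min,call_rate_min,maf_min Thresholds in (0, 1).
#' @export
qc_thresholds <- function(info_min = 0.5, hwe_p_min = 1e-4,
                          call_rate_min = 0.95, maf_min = 0.01) {
  thr <- list(info_min = info_min, hwe_p_min = hwe_p_min,
              call_rate_min = call_rate_min, maf_min = maf_min)
  for (f in names(thr)) check_range(thr[[f]], 0, 1, f, lo_open = TRUE, hi_open = TRUE)
  structure(thr, class = "QCThresholds")
}

#' Filter variants on QC metadata
#'
#' Retains exactly the variants with info >= `info_min` AND
#' HWE P >= `hwe_p_min` AND call rate >= `call_rate_min` AND
#' MAF >= `maf_min` (all boundaries inclusive: a variant exactly at every
#' threshold is kept). Idempotent.
#'
#' @param G A [genotype_matrix()].
#' @param thr A [qc_thresholds()].
#' @return The filtered `GenotypeMatrix`, with attribute `removed`
#'   giving the per-criterion removal counts (a variant failing several
#'   criteria is counted under each).
#' @export
filter_variants <- function(G, thr = qc_thresholds()) {
  va <- G$variants
  need <- c("info", "hwe_p", "call_rate", "maf")
  if (!all(need %in% names(va)) || anyNA(va[need]))
    stopf("variant QC metadata (info, hwe_p, call_rate, maf) must be populated")
  fail <- cbind(info = va$info < thr$info_min,
                hwe_p = va$hwe_p < thr$hwe_p_min,
                call_rate = va$call_rate < thr$call_rate_min,
                maf = va$maf < thr$maf_min)
  keep <- !apply(fail, 1L, any)
  out <- genotype_matrix(G$dosages[, keep, drop = FALSE],
                         va[keep, , drop = FALSE])
  attr(out, "removed") <- as.integer(colSums(fail))
  names(attr(out, "removed")) <- colnames(fail)
  out
}

#' Rank-based inverse-normal transformation
#'
#' Blom-offset transform `qnorm((rank - 3/8) / (n + 1/4))`, applied
#' within each cohort independently; ties take the average rank. Any
#' strictly monotone transform of the input yields identical output.
#'
#' @param values Numeric vector.
#' @param cohort Optional cohort labels (same length); `NULL` treats all
#'   values as one cohort.
#' @return Transformed vector (within-cohort mean approximately 0).
#' @export
rank_inverse_normal <- function(values, cohort = NULL) {
  if (is.null(cohort)) cohort <- rep(1L, length(values))
  if (length(cohort) != length(values)) stopf("cohort labels must match values")
  if (anyNA(values)) stopf("missing values are not supported")
  out <- numeric(length(values))
  for (ch in unique(cohort)) {
    idx <- which(cohort == ch)
    v <- values[idx]
    if (length(unique(v)) < 2L)
      stopf("cohort '%s' has a constant value vector; rank transform undefined", ch)
    r <- rank(v, ties.method = "average")
    out[idx] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  }
  out
}

#' Inverse-normal transform every feature of a trait matrix
#'
#' @param Y A [trait_matrix()].
#' @param C A [covariate_bundle()] supplying the cohort labels.
#' @return A [trait_matrix()] with `scale_tag = "normalized"`.
#' @export
int_transform <- function(Y, C) {
  if (!identical(rownames(Y$values), C$data$sample_id))
    stopf("trait and covariate samples do not match")
  V <- apply(Y$values, 2L, rank_inverse_normal, cohort = C$data$cohort)
  dimnames(V) <- dimnames(Y$values)
  trait_matrix(V, Y$features, scale_tag = "normalized")
}

#' Build the covariate design matrix
#'
#' Intercept + age + six cell counts + reference-coded indicators for
#' sex, cohort and batch (factors with a single level are dropped) +
#' latent factor scores when requested. The design is checked for full
#' column rank; collinear columns are named in the error.
#'
#' @param C A [covariate_bundle()].
#' @param include_latent Include the latent factor columns.
#' @param extra Optional named list/matrix of extra numeric columns
#'   (e.g. sentinel dosages to condition on).
#' @return Numeric design matrix with an `(Intercept)` column.
#' @export
build_design <- function(C, include_latent = TRUE, extra = NULL) {
  d <- C$data
  X <- cbind(`(Intercept)` = rep(1, nrow(d)), age = d$age,
             as.matrix(d[cell_count_names()]))
  droppable <- character(0)
  for (f in c("sex", "cohort", "batch")) {
    v <- factor(d[[f]])
    if (nlevels(v) > 1L) {
      mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(f, levels(v)[-1L])
      ## indicator blocks may alias each other when factors are nested
      ## (batch within cohort); those aliased columns are removable
      droppable <- c(droppable, colnames(mm))
      X <- cbind(X, mm)
    }
  }
  if (include_latent && ncol(C$latent) > 0) X <- cbind(X, C$latent)
  if (!is.null(extra)) {
    extra <- as.matrix(as.data.frame(extra))
    rownames(extra) <- NULL
    X <- cbind(X, extra)
  }
  rownames(X) <- d$sample_id
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qr_X$pivot[seq_len(qr_X$rank)])]
    if (all(bad %in% droppable)) {
      message(sprintf("build_design: dropping aliased indicator column(s): %s",
                      paste(bad, collapse = ", ")))
      X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    } else {
      stopf("design matrix is rank deficient; collinear column(s): %s",
            paste(bad, collapse = ", "))
    }
  }
  X
}

#' Residualize traits on known covariates
#'
#' Per feature, OLS residuals after regressing on the [build_design()]
#' covariates (optionally including latent factors). Residuals are
#' orthogonal to every design column.
#'
#' @param Y A [trait_matrix()] or numeric matrix.
#' @param C A [covariate_bundle()].
#' @param include_latent Include latent factors in the design.
#' @param extra Extra design columns (see [build_design()]).
#' @return Object of the same type as `Y` (trait matrices come back with
#'   `scale_tag = "normalized"`), with attribute `design`.
#' @export
residualize <- function(Y, C, include_latent = TRUE, extra = NULL) {
  V <- if (inherits(Y, "TraitMatrix")) Y$values else Y
  if (!identical(rownames(V), C$data$sample_id))
    stopf("trait and covariate samples do not match")
  X <- build_design(C, include_latent = include_latent, extra = extra)
  R <- qr.resid(qr(X), V)
  dimnames(R) <- dimnames(V)
  out <- if (inherits(Y, "TraitMatrix"))
    trait_matrix(R, Y$features, scale_tag = "normalized") else R
  attr(out, "design") <- X
  out
}

#' Estimate latent confounder factors
#'
#' Principal-component scores of the feature-standardized residual
#' matrix. With `q = "auto"`, the factor count is chosen by the
#' eigenvalue-difference rule: `q = argmax_k (lambda_k - lambda_{k+1})`
#' over `k = 1..q_max` of the sample covariance spectrum. Scores have
#' unit variance per factor. Because factors are estimated from
#' covariate residuals, they are orthogonal to the known covariates by
#' construction.
#'
#' @param Y_resid Residualized trait matrix ([residualize()] output) or
#'   numeric matrix.
#' @param q Number of factors, or `"auto"`.
#' @param q_max Upper bound for the automatic search.
#' @return Numeric matrix of scores (samples x q; q may be 0), with
#'   attribute `eigenvalues`.
#' @export
estimate_latent_factors <- function(Y_resid, q = "auto", q_max = 10) {
  V <- if (inherits(Y_resid, "TraitMatrix")) Y_resid$values else Y_resid
  n <- nrow(V); p <- ncol(V)
  if (!identical(q, "auto")) {
    if (!is_count(q)) stopf("q must be a nonnegative count or 'auto'")
    if (q > min(n, p)) stopf("q = %d exceeds min(n_samples, n_features) = %d",
                             q, min(n, p))
  }
  sds <- apply(V, 2L, stats::sd)
  keep <- sds > 0
  Z <- scale(V[, keep, drop = FALSE])
  sv <- svd(Z, nu = min(n, q_max + 1L, sum(keep)), nv = 0)
  lambda <- sv$d^2 / (n - 1)
  if (identical(q, "auto")) {
    kmax <- min(q_max, length(lambda) - 1L)
    diffs <- lambda[seq_len(kmax)] - lambda[seq_len(kmax) + 1L]
    q <- which.max(diffs)
  }
  if (q == 0) {
    scores <- matrix(numeric(0), n, 0, dimnames = list(rownames(V), NULL))
  } else {
    scores <- sv$u[, seq_len(q), drop = FALSE]
    scores <- scale(scores, center = TRUE, scale = apply(scores, 2L, stats::sd))
    attr(scores, "scaled:center") <- NULL
    attr(scores, "scaled:scale") <- NULL
    dimnames(scores) <- list(rownames(V), paste0("LF", seq_len(q)))
  }
  attr(scores, "eigenvalues") <- lambda
  scores
}

#' Replace the latent factors of a covariate bundle
#'
#' @param C A [covariate_bundle()].
#' @param scores Latent score matrix (samples x q), e.g. from
#'   [estimate_latent_factors()].
#' @return Updated `CovariateBundle`.
#' @export
set_latent_factors <- function(C, scores) {
  covariate_bundle(C$data, latent = if (ncol(scores) > 0) scores else NULL)
}

#' Mean-impute missing dosages
#'
#' OLS needs complete genotype vectors; missing dosages are replaced by
#' the per-variant mean and the imputed count reported.
#'
#' @param G A [genotype_matrix()].
#' @return `GenotypeMatrix` without missing dosages.
#' @export
impute_missing_dosages <- function(G) {
  n_na <- sum(is.na(G$dosages))
  if (n_na > 0) {
    mu <- colMeans(G$dosages, na.rm = TRUE)
    idx <- which(is.na(G$dosages), arr.ind = TRUE)
    G$dosages[idx] <- mu[idx[, 2L]]
    message(sprintf("impute_missing_dosages: mean-imputed %d dosage values", n_na))
  }
  G
}
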