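## Multi-cohort replication: per-cohort simple-regression t statistics,
## Stouffer's sample-size-weighted Z combination per CpG, Simes per
## variant, Bonferroni across the sentinels carried to replication.

#' Per-cohort association of one variant with all CpGs
#'
#' Within each cohort, the per-CpG t statistic of the regression
#' `y = beta x` (no covariates by default, matching the replication
#' model; traits are expected to be pre-normalized within cohort).
#'
#' @param x Dosage vector on the replication sample.
#' @param Y Trait matrix (normalized within cohort).
#' @param cohort Cohort labels per sample.
#' @param covariates Optional numeric design columns added to the
#'   per-cohort model.
#' @return List of `CohortStat`: per cohort, `cohort_id`, `n` (the
#'   Stouffer weight) and `t` (per-CpG t vector; `NA` where the dosage
#'   has no variance within the cohort).
#' @export
per_cohort_assoc <- function(x, Y, cohort, covariates = NULL) {
  V <- if (inherits(Y, "TraitMatrix")) Y$values else Y
  if (length(x) != nrow(V) || length(cohort) != nrow(V))
    stopf("x, cohort and traits must have matching samples")
  out <- list()
  for (ch in unique(cohort)) {
    idx <- which(cohort == ch)
    if (length(idx) < 2L) stopf("cohort '%s' has fewer than 2 samples", ch)
    design <- cbind(`(Intercept)` = rep(1, length(idx)),
                    if (!is.null(covariates)) as.matrix(covariates)[idx, , drop = FALSE])
    xc <- x[idx]
    if (stats::sd(xc) == 0) {
      tvec <- rep(NA_real_, ncol(V))
    } else {
      res <- assoc_core(matrix(xc, ncol = 1L), V[idx, , drop = FALSE], design)
      tvec <- res$t[1L, ]
    }
    out[[ch]] <- list(cohort_id = ch, n = length(idx),
                      t = stats::setNames(tvec, colnames(V)))
  }
  out
}

#' Stouffer's weighted-Z combination
#'
#' `Z = sum_k(w_k t_k) / sqrt(sum_k w_k^2)` with weights `w_k` = cohort
#' sample size; cohorts with a missing statistic are excluded from both
#' sums. The per-cohort t statistics are treated as z-scores, which is
#' accurate for the large per-cohort samples the method is meant for.
#'
#' @param t Vector (one CpG) or matrix (cohorts x CpGs) of t statistics.
#' @param w Cohort weights (sample sizes).
#' @return Combined z (scalar or per-CpG vector); `NA` where every
#'   cohort is missing.
#' @export
stouffer_combine <- function(t, w) {
  ## vector input: one t statistic per cohort (a single CpG)
  t <- if (is.matrix(t)) t else matrix(t, ncol = 1L)
  if (length(w) != nrow(t)) stopf("one weight per cohort is required")
  W <- matrix(w, nrow(t), ncol(t))
  W[is.na(t)] <- 0
  t0 <- t
  t0[is.na(t)] <- 0
  denom <- sqrt(colSums(W^2))
  z <- colSums(W * t0) / denom
  z[denom == 0] <- NA_real_
  if (length(z) == 1L) unname(z) else z
}

#' Replicate sentinel variants across cohorts
#'
#' For each sentinel: per-cohort per-CpG t statistics, Stouffer
#' combination into per-CpG z, two-sided normal p, Simes into one
#' overall replication P per sentinel, and Bonferroni adjustment across
#' the number of sentinels tested.
#'
#' @param sentinel_ids Variant ids carried to replication.
#' @param G Replication [genotype_matrix()].
#' @param Y Replication trait matrix (normalized within cohort).
#' @param C Replication [covariate_bundle()] (supplies cohort labels).
#' @param covariates Optional per-cohort model covariates.
#' @return List with `summary` (per sentinel: `overall_p`,
#'   `adjusted_p`, `n_cohorts`) and `meta` (per sentinel x CpG: `z`,
#'   `p`).
#' @export
replicate_sentinels <- function(sentinel_ids, G, Y, C, covariates = NULL) {
  if (!all(sentinel_ids %in% colnames(G$dosages)))
    stopf("sentinel(s) absent from replication genotypes: %s",
          paste(setdiff(sentinel_ids, colnames(G$dosages)), collapse = ", "))
  V <- if (inherits(Y, "TraitMatrix")) Y$values else Y
  cohort <- C$data$cohort
  n_tested <- length(sentinel_ids)
  meta <- list()
  summ <- list()
  for (sid in sentinel_ids) {
    cs <- per_cohort_assoc(G$dosages[, sid], Y, cohort, covariates = covariates)
    tmat <- do.call(rbind, lapply(cs, `[[`, "t"))
    w <- vapply(cs, `[[`, numeric(1), "n")
    z <- stouffer_combine(tmat, w)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    meta[[sid]] <- data.frame(variant_id = sid, feature_id = colnames(V),
                              z = z, p = p, stringsAsFactors = FALSE,
                              row.names = NULL)
    ok <- !is.na(p)
    overall <- if (any(ok)) simes_combine(pmax(p[ok], .Machine$double.xmin)) else NA_real_
    summ[[sid]] <- data.frame(variant_id = sid, overall_p = overall,
                              adjusted_p = min(1, overall * n_tested),
                              n_cohorts = length(cs), n_tests = sum(ok),
                              stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       meta = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}
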