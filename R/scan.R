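## The discovery engine: Simes-combined global scan, iterative
## conditional locus discovery, male validation with LD proxies,
## genotype-by-sex interaction, per-CpG FDR effect lists, and the
## direction-consistency sign test.

#' Simes combination of p-values
#'
#' `P = min_j ( m * p_(j) / j )` over the sorted p-values, capped at 1.
#' A valid global test of the joint null under independence or positive
#' dependence; satisfies `min(p) <= P <= m * min(p)`.
#'
#' @param pvals Vector of two-sided p-values in (0, 1\].
#' @return The combined overall P-value.
#' @export
simes_combine <- function(pvals) {
  if (length(pvals) == 0L) stopf("simes_combine needs at least one p-value")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stopf("p-values must lie in (0, 1]")
  m <- length(pvals)
  min(1, min(m * sort(pvals) / seq_len(m)))
}

## Simes with the index of the feature attaining the minimum
simes_detail <- function(pvals) {
  m <- length(pvals)
  o <- order(pvals)
  vals <- m * pvals[o] / seq_len(m)
  k <- which.min(vals)
  list(p = min(1, vals[k]), argmin = o[k])
}

#' Global scan of a variant panel against a trait matrix
#'
#' For every variant, per-CpG Wald tests (model
#' `y = beta x + gamma M + delta U`, optionally plus conditioning
#' covariates) are combined into one overall P-value with the Simes
#' procedure, turning the scan into a single GWAS for trait variation
#' anywhere on the chromosome. Variants whose dosages are collinear with
#' the design (e.g. already conditioned on) get `overall_p = NA`.
#'
#' @param G A [genotype_matrix()].
#' @param Y A [trait_matrix()] (normalized scale for inference).
#' @param C A [covariate_bundle()].
#' @param alpha Genome-wide significance threshold on the overall P
#'   (default 5e-8).
#' @param include_latent Include latent factor covariates.
#' @param condition_on Optional named list/matrix of sentinel dosages to
#'   condition on.
#' @return List with `records` (data frame: `variant_id`, `overall_p`,
#'   `n_tests`, `argmin_feature`, `min_p`), `significant` (variant ids
#'   with `overall_p < alpha`), and `alpha`.
#' @export
global_scan <- function(G, Y, C, alpha = 5e-8, include_latent = TRUE,
                        condition_on = NULL) {
  V <- if (inherits(Y, "TraitMatrix")) Y$values else Y
  if (!identical(rownames(G$dosages), rownames(V)) ||
      !identical(rownames(V), C$data$sample_id))
    stopf("genotypes, traits and covariates must be sample-aligned")
  design <- build_design(C, include_latent = include_latent, extra = condition_on)
  res <- assoc_core(G$dosages, V, design)
  m <- ncol(V)
  records <- data.frame(variant_id = colnames(G$dosages),
                        overall_p = NA_real_, n_tests = m,
                        argmin_feature = NA_character_, min_p = NA_real_,
                        stringsAsFactors = FALSE)
  ok <- which(!res$dropped)
  for (i in ok) {
    sd_i <- simes_detail(res$p[i, ])
    records$overall_p[i] <- sd_i$p
    records$argmin_feature[i] <- colnames(V)[sd_i$argmin]
    records$min_p[i] <- min(res$p[i, ])
  }
  sig <- records$variant_id[!is.na(records$overall_p) & records$overall_p < alpha]
  list(records = records, significant = sig, alpha = alpha)
}

#' Iterative conditional locus discovery
#'
#' Repeats the global scan, each round conditioning on all previously
#' discovered sentinel variants, and adds the variant with the lowest
#' overall P as the next sentinel while that P stays below `alpha`.
#' Conditioning removes the signal of LD proxies, so each locus is
#' reported once.
#'
#' @inheritParams global_scan
#' @param max_iter Hard iteration cap guaranteeing termination.
#' @return Data frame of class `LocusTable`: `sentinel_variant_id`,
#'   `iteration`, `conditioned_on` (comma-joined prior sentinels),
#'   `overall_p_at_discovery`.
#' @export
conditional_scan <- function(G, Y, C, alpha = 5e-8, include_latent = TRUE,
                             max_iter = 100L) {
  sentinels <- character(0)
  loci <- list()
  for (it in seq_len(max_iter)) {
    cond <- if (length(sentinels))
      G$dosages[, sentinels, drop = FALSE] else NULL
    sc <- tryCatch(
      global_scan(G, Y, C, alpha = alpha, include_latent = include_latent,
                  condition_on = cond),
      error = function(e) {
        warnf("conditional iteration %d failed (%s); stopping", it, conditionMessage(e))
        NULL
      })
    if (is.null(sc)) break
    rec <- sc$records[!is.na(sc$records$overall_p) &
                        !(sc$records$variant_id %in% sentinels), , drop = FALSE]
    if (nrow(rec) == 0L) break
    best <- rec[order(rec$overall_p, rec$variant_id), ][1L, ]
    if (best$overall_p >= alpha) break
    loci[[it]] <- data.frame(sentinel_variant_id = best$variant_id,
                             iteration = it,
                             conditioned_on = paste(sentinels, collapse = ","),
                             overall_p_at_discovery = best$overall_p,
                             stringsAsFactors = FALSE)
    sentinels <- c(sentinels, best$variant_id)
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(sentinel_variant_id = character(0), iteration = integer(0),
               conditioned_on = character(0),
               overall_p_at_discovery = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("LocusTable", class(out))
  out
}

#' Female-specificity validation in the male stratum
#'
#' For each locus, the sentinel and every LD proxy (dosage r-squared >=
#' `proxy_r2` within `proxy_window` of the sentinel, computed in males)
#' is scanned in males; a locus with any of these variants reaching an
#' overall P <= `male_alpha` is not female-specific. The minimum per-CpG
#' Wald p of the sentinel is additionally compared against
#' `male_replication_alpha` to report which loci replicate in males.
#'
#' @param loci A [conditional_scan()] locus table.
#' @param G_male,Y_male,C_male Male-stratum data (sample-aligned).
#' @param proxy_window Maximum sentinel-proxy distance (bp).
#' @param proxy_r2 Minimum squared dosage correlation for a proxy.
#' @param male_alpha Overall-P threshold excluding female-specificity.
#' @param male_replication_alpha Per-CpG Wald threshold for reporting
#'   male replication.
#' @param include_latent Include latent factors in the male model.
#' @return Data frame: one `FemaleSpecificityReport` row per locus.
#' @export
male_validation <- function(loci, G_male, Y_male, C_male,
                            proxy_window = 1e6, proxy_r2 = 0.8,
                            male_alpha = 0.05,
                            male_replication_alpha = 1.1e-6,
                            include_latent = TRUE) {
  if (nrow(C_male$data) == 0L) stopf("male stratum is empty")
  va <- G_male$variants
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    sid <- loci$sentinel_variant_id[i]
    si <- match(sid, va$id)
    if (is.na(si)) stopf("sentinel %s absent from male genotypes", sid)
    near <- which(va$chrom == va$chrom[si] &
                    abs(va$pos - va$pos[si]) <= proxy_window & va$id != sid)
    r2 <- if (length(near))
      suppressWarnings(stats::cor(G_male$dosages[, si], G_male$dosages[, near],
                                  use = "pairwise.complete.obs"))^2 else numeric(0)
    proxies <- va$id[near[!is.na(r2) & r2 >= proxy_r2]]
    test_ids <- c(sid, proxies)
    Gs <- genotype_matrix(G_male$dosages[, test_ids, drop = FALSE],
                          va[match(test_ids, va$id), , drop = FALSE])
    sc <- global_scan(Gs, Y_male, C_male, alpha = male_alpha,
                      include_latent = include_latent)
    p_min <- suppressWarnings(min(sc$records$overall_p, na.rm = TRUE))
    wald_min <- sc$records$min_p[sc$records$variant_id == sid]
    out[[i]] <- data.frame(
      sentinel_variant_id = sid,
      male_overall_p_min = p_min,
      n_proxies = length(proxies),
      female_specific = p_min > male_alpha,
      male_min_wald_p = wald_min,
      replicates_in_males = !is.na(wald_min) && wald_min < male_replication_alpha,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Genotype-by-sex interaction test
#'
#' Per CpG, fits `y = b1 x + b2 sex + b3 (x * sex) + gamma M + delta U`
#' on the combined-sex sample and Wald-tests the interaction coefficient
#' `b3`; the per-CpG interaction p-values are combined with the Simes
#' procedure.
#'
#' @param x Dosage vector on the combined sample.
#' @param Y Trait matrix on the combined sample.
#' @param C Covariates (must contain both sexes; sex enters the design).
#' @param include_latent Include latent factors.
#' @return List with `overall_p` (Simes-combined) and `per_cpg` (data
#'   frame of interaction statistics).
#' @export
interaction_test <- function(x, Y, C, include_latent = TRUE) {
  V <- if (inherits(Y, "TraitMatrix")) Y$values else Y
  sexes <- unique(C$data$sex)
  if (length(sexes) < 2L) stopf("interaction test requires both sexes")
  design <- build_design(C, include_latent = include_latent,
                         extra = list(dosage = x))
  inter <- x * (C$data$sex == "male")
  res <- assoc_core(matrix(inter, ncol = 1L), V, design)
  if (res$dropped[1L]) stopf("interaction term collinear with design")
  per_cpg <- data.frame(feature_id = colnames(V), beta = res$beta[1L, ],
                        se = res$se[1L, ], t_stat = res$t[1L, ],
                        df = res$df, p = res$p[1L, ],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(overall_p = simes_combine(per_cpg$p), per_cpg = per_cpg)
}

#' Per-CpG effect list for a sentinel at a given FDR
#'
#' Benjamini-Hochberg across the sentinel's per-CpG p-vector (computed
#' on the normalized scale); CpGs with q < `fdr` are returned with their
#' effect sign, and the effect size is re-estimated on the raw beta
#' scale with the same covariates so it is reported as % methylation per
#' allele.
#'
#' @param x Sentinel dosage vector.
#' @param Y_norm Normalized-scale trait matrix (inference).
#' @param Y_beta Beta-scale trait matrix (effect reporting).
#' @param C Covariates.
#' @param fdr FDR threshold.
#' @param include_latent Include latent factors.
#' @param extra Extra design columns (e.g. other sentinels).
#' @return List with `effects` (all CpGs: `p`, `q`, `beta_norm`,
#'   `beta_raw`, `significant`), `significant` (the q < fdr subset) and
#'   `direction` (sign counts plus the exact sign-test p of the
#'   significant set).
#' @export
per_cpg_effects <- function(x, Y_norm, Y_beta, C, fdr = 0.05,
                            include_latent = TRUE, extra = NULL) {
  a_norm <- wald_assoc(x, Y_norm, C, include_latent = include_latent, extra = extra)
  a_beta <- wald_assoc(x, Y_beta, C, include_latent = include_latent, extra = extra)
  q <- stats::p.adjust(a_norm$p, method = "BH")
  eff <- data.frame(feature_id = a_norm$feature_id,
                    beta_norm = a_norm$beta, se_norm = a_norm$se,
                    p = a_norm$p, q = q,
                    beta_raw = a_beta$beta, se_raw = a_beta$se,
                    significant = q < fdr, stringsAsFactors = FALSE)
  sig <- eff[eff$significant, , drop = FALSE]
  n_neg <- sum(sig$beta_raw < 0)
  n_pos <- sum(sig$beta_raw > 0)
  dir_p <- if (nrow(sig)) direction_consistency_test(sign(sig$beta_raw)) else NA_real_
  list(effects = eff, significant = sig,
       direction = list(n_pos = n_pos, n_neg = n_neg,
                        consistency = if (nrow(sig)) max(n_pos, n_neg) / nrow(sig) else NA_real_,
                        sign_test_p = dir_p))
}

#' Exact two-sided sign test of direction consistency
#'
#' Tests whether effect signs depart from a fair coin: with `k` of the
#' `n` signs in the majority direction, `p = min(1, 2 * min(P(X <= k),
#' P(X >= k)))` under Binomial(n, 1/2), the tail evaluated at the
#' observed positive count.
#'
#' @param signs Vector of effect signs (any encoding; positive values
#'   count as successes). Alternatively supply `k` and `n` directly.
#' @param k,n Success count and trial count (used when `signs` is NULL).
#' @return Exact two-sided sign-test p-value.
#' @export
direction_consistency_test <- function(signs = NULL, k = NULL, n = NULL) {
  if (!is.null(signs)) {
    signs <- signs[signs != 0]
    n <- length(signs)
    k <- sum(signs > 0)
  }
  if (is.null(k) || is.null(n)) stopf("supply signs, or k and n")
  if (n < 1) stopf("need at least one sign")
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
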