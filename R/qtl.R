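## QTL mapping around discovered loci: cis-eQTL (variant -> nearby gene
## expression), CpG -> nearby expression coupling, long-range trans
## meQTL on autosomal CpGs, X-chromosomal cis-meQTL lookup, and the
## epistasis check re-estimating a trans effect adjusted for the
## strongest X cis-SNP.

#' Distance windows used throughout the pipeline
#'
#' @param cis_window cis window each side (bp; closed, a feature exactly
#'   at the boundary is included).
#' @param trans_min_distance Minimum same-chromosome distance for a
#'   trans pair (strictly greater than); different chromosomes are
#'   always trans.
#' @param escape_tss_max_distance Maximum CpG-TSS distance for escape
#'   annotation.
#' @param proxy_window LD proxy search window around a sentinel.
#' @export
window_spec <- function(cis_window = 250000, trans_min_distance = 5e6,
                        escape_tss_max_distance = 10000, proxy_window = 1e6) {
  if (any(c(cis_window, trans_min_distance, escape_tss_max_distance,
            proxy_window) <= 0))
    stopf("all windows must be positive")
  if (cis_window >= trans_min_distance)
    stopf("cis_window must be smaller than trans_min_distance")
  structure(list(cis_window = cis_window,
                 trans_min_distance = trans_min_distance,
                 escape_tss_max_distance = escape_tss_max_distance,
                 proxy_window = proxy_window), class = "WindowSpec")
}

## features within the closed cis window of an anchor position
features_in_cis <- function(features, chrom, pos, window) {
  d <- interval_distance(pos, features$start, features$end)
  which(features$chrom == chrom & d <= window)
}

#' cis-eQTL mapping for one variant
#'
#' Tests every gene whose interval lies within the cis window of the
#' variant position (distance measured to the gene interval, 0 inside),
#' model `expression = beta x + gamma M + delta U`, Bonferroni-corrected
#' across the genes tested for this variant.
#'
#' @param variant_id Variant to map.
#' @param G Genotypes containing the variant.
#' @param E Expression [trait_matrix()] with gene intervals.
#' @param C Covariates.
#' @param windows A [window_spec()].
#' @param include_latent Include latent factors (the printed cis-eQTL
#'   model has them).
#' @param alpha Significance level applied to the Bonferroni-adjusted p.
#' @return `AssocStat` data frame with `p_bonferroni` and `significant`
#'   columns; zero rows (with a warning) when no gene is in the window.
#' @export
cis_eqtl <- function(variant_id, G, E, C, windows = window_spec(),
                     include_latent = TRUE, alpha = 0.05) {
  vi <- match(variant_id, G$variants$id)
  if (is.na(vi)) stopf("variant %s not found", variant_id)
  idx <- features_in_cis(E$features, G$variants$chrom[vi], G$variants$pos[vi],
                         windows$cis_window)
  if (length(idx) == 0L) {
    warnf("no genes within %d bp of %s", windows$cis_window, variant_id)
    return(data.frame(feature_id = character(0), beta = numeric(0),
                      se = numeric(0), t_stat = numeric(0), df = integer(0),
                      p = numeric(0), p_bonferroni = numeric(0),
                      significant = logical(0)))
  }
  Es <- trait_matrix(E$values[, idx, drop = FALSE],
                     E$features[idx, , drop = FALSE], scale_tag = E$scale_tag)
  out <- wald_assoc(G$dosages[, vi], Es, C, include_latent = include_latent)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Associate CpG methylation with nearby gene expression
#'
#' Same windowed test anchored on the CpG position, with the CpG's
#' methylation as the predictor of expression; known covariates only
#' (no latent factors) by default, matching the printed model.
#'
#' @param cpg_id CpG to anchor on.
#' @param Y Methylation trait matrix containing the CpG.
#' @param E Expression trait matrix.
#' @param C Covariates.
#' @param windows A [window_spec()].
#' @param include_latent Default `FALSE`.
#' @param alpha Level for the Bonferroni-adjusted p.
#' @return As [cis_eqtl()].
#' @export
cpg_expression_assoc <- function(cpg_id, Y, E, C, windows = window_spec(),
                                 include_latent = FALSE, alpha = 0.05) {
  ci <- match(cpg_id, Y$features$id)
  if (is.na(ci)) stopf("CpG %s not found", cpg_id)
  idx <- features_in_cis(E$features, Y$features$chrom[ci], Y$features$start[ci],
                         windows$cis_window)
  if (length(idx) == 0L) {
    warnf("no genes within %d bp of %s", windows$cis_window, cpg_id)
    return(data.frame(feature_id = character(0), beta = numeric(0),
                      se = numeric(0), t_stat = numeric(0), df = integer(0),
                      p = numeric(0), p_bonferroni = numeric(0),
                      significant = logical(0)))
  }
  Es <- trait_matrix(E$values[, idx, drop = FALSE],
                     E$features[idx, , drop = FALSE], scale_tag = E$scale_tag)
  out <- wald_assoc(Y$values[, ci], Es, C, include_latent = include_latent)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Long-range trans-meQTL mapping for one variant
#'
#' Tests autosomal CpGs on other chromosomes, or farther than
#' `trans_min_distance` on the variant's own chromosome, on the combined
#' sample (sex among the covariates); Benjamini-Hochberg within this
#' variant's p-vector.
#'
#' @param variant_id Variant to map.
#' @param G Genotypes.
#' @param Y_auto Autosomal methylation trait matrix (normalized scale).
#' @param C Covariates (combined sexes).
#' @param windows A [window_spec()].
#' @param fdr FDR threshold.
#' @param include_latent Include latent factors.
#' @return `AssocStat` data frame with `q` and `significant` columns
#'   (all tested CpGs; filter on `significant` for the FDR list).
#' @export
trans_meqtl <- function(variant_id, G, Y_auto, C, windows = window_spec(),
                        fdr = 0.05, include_latent = TRUE) {
  vi <- match(variant_id, G$variants$id)
  if (is.na(vi)) stopf("variant %s not found", variant_id)
  feat <- Y_auto$features
  d <- interval_distance(G$variants$pos[vi], feat$start, feat$end)
  idx <- which(feat$chrom != G$variants$chrom[vi] | d > windows$trans_min_distance)
  Ys <- trait_matrix(Y_auto$values[, idx, drop = FALSE],
                     feat[idx, , drop = FALSE], scale_tag = Y_auto$scale_tag)
  out <- wald_assoc(G$dosages[, vi], Ys, C, include_latent = include_latent)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out
}

#' Strongest X-chromosomal cis-meQTL per CpG
#'
#' For each CpG, tests all X variants within the cis window (known
#' covariates only) and returns the strongest Bonferroni-significant
#' cis-SNP, or none; ties broken toward the lower variant position.
#'
#' @param cpg_ids CpGs to map.
#' @param G_x X-chromosome genotypes.
#' @param Y_x X methylation trait matrix (normalized scale).
#' @param C Covariates.
#' @param windows A [window_spec()].
#' @param alpha Level on the Bonferroni-adjusted p.
#' @param include_latent Default `FALSE` (the epistasis model uses known
#'   covariates only).
#' @return Data frame per CpG: `cpg_id`, `cis_snp_id` (`NA` if none),
#'   `p`, `p_bonferroni`, `n_tested`.
#' @export
cis_meqtl_x <- function(cpg_ids, G_x, Y_x, C, windows = window_spec(),
                        alpha = 0.05, include_latent = FALSE) {
  feat <- Y_x$features
  va <- G_x$variants
  out <- vector("list", length(cpg_ids))
  for (k in seq_along(cpg_ids)) {
    cid <- cpg_ids[k]
    ci <- match(cid, feat$id)
    if (is.na(ci)) stopf("CpG %s not found", cid)
    idx <- which(va$chrom == feat$chrom[ci] &
                   abs(va$pos - feat$start[ci]) <= windows$cis_window)
    if (length(idx) == 0L) {
      out[[k]] <- data.frame(cpg_id = cid, cis_snp_id = NA_character_,
                             p = NA_real_, p_bonferroni = NA_real_,
                             n_tested = 0L, stringsAsFactors = FALSE)
      next
    }
    design <- build_design(C, include_latent = include_latent)
    res <- assoc_core(G_x$dosages[, idx, drop = FALSE],
                      Y_x$values[, ci, drop = FALSE], design)
    p <- res$p[, 1L]
    padj <- pmin(1, p * length(idx))
    sig <- which(!is.na(padj) & padj < alpha)
    if (length(sig) == 0L) {
      out[[k]] <- data.frame(cpg_id = cid, cis_snp_id = NA_character_,
                             p = NA_real_, p_bonferroni = NA_real_,
                             n_tested = length(idx), stringsAsFactors = FALSE)
    } else {
      best <- sig[order(p[sig], va$pos[idx[sig]])][1L]
      out[[k]] <- data.frame(cpg_id = cid, cis_snp_id = va$id[idx[best]],
                             p = p[best], p_bonferroni = padj[best],
                             n_tested = length(idx), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Trans effect re-estimated with the strongest cis-SNP as covariate
#'
#' The epistasis check: the autosomal variant's effect on an X CpG is
#' re-fit with the CpG's strongest X cis-meQTL SNP added to the
#' covariates. With no cis-SNP the adjusted estimate equals the
#' unadjusted one exactly.
#'
#' @param variant_id Autosomal variant.
#' @param cpg_id X CpG.
#' @param cis_snp_id Strongest cis-SNP from [cis_meqtl_x()], or `NA`.
#' @param G,G_x Autosomal / X genotypes.
#' @param Y_x X methylation (normalized scale).
#' @param C Covariates.
#' @param include_latent Default `FALSE` (matching the epistasis model).
#' @return One-row data frame: `beta_unadjusted`, `beta_adjusted`,
#'   `p_adjusted`, plus ids.
#' @export
adjusted_trans_effect <- function(variant_id, cpg_id, cis_snp_id, G, G_x, Y_x,
                                  C, include_latent = FALSE) {
  vi <- match(variant_id, G$variants$id)
  ci <- match(cpg_id, Y_x$features$id)
  if (is.na(vi) || is.na(ci)) stopf("variant or CpG not found")
  x <- G$dosages[, vi]
  y <- Y_x$values[, ci, drop = FALSE]
  base <- wald_assoc(x, y, C, include_latent = include_latent)
  if (is.na(cis_snp_id)) {
    return(data.frame(variant_id = variant_id, cpg_id = cpg_id,
                      cis_snp_id = NA_character_,
                      beta_unadjusted = base$beta, beta_adjusted = base$beta,
                      p_adjusted = base$p, stringsAsFactors = FALSE))
  }
  si <- match(cis_snp_id, G_x$variants$id)
  if (is.na(si)) stopf("cis SNP %s not found in X genotypes", cis_snp_id)
  xc <- G_x$dosages[, si]
  if (abs(stats::cor(x, xc)) > 0.999)
    stopf("cis SNP %s is collinear with variant %s: unlinked chromosomes cannot share dosage; data corruption likely",
          cis_snp_id, variant_id)
  adj <- wald_assoc(x, y, C, include_latent = include_latent,
                    extra = list(cis_snp = xc))
  data.frame(variant_id = variant_id, cpg_id = cpg_id, cis_snp_id = cis_snp_id,
             beta_unadjusted = base$beta, beta_adjusted = adj$beta,
             p_adjusted = adj$p, stringsAsFactors = FALSE)
}
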