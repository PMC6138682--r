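## Synthetic study generator with planted, recoverable ground truth.
## Emulates the statistical structure the discovery pipeline assumes:
## Hardy-Weinberg genotypes at configurable MAF, beta-scale methylation
## with CpG-specific baselines, female-only per-allele effects at planted
## CpG sets, cell-count / batch / cohort / latent-factor confounding, a
## multi-cohort sample, and annotation tracks in which affected CpGs are
## preferentially placed in CpG islands and variable-escape intervals.

#' Describe a planted locus
#'
#' @param variant_index Index (1-based) of the variant carrying the
#'   effect, within the simulated autosomal variant panel.
#' @param maf Minor allele frequency of the planted variant.
#' @param target_cpg_indices Indices of affected X-chromosomal CpGs.
#' @param per_allele_effect_beta Effect per alternative allele on the
#'   methylation beta scale (e.g. -0.015 = 1.5% hypomethylation per
#'   allele, the magnitude scale of blood meQTL effects).
#' @param female_specific If `TRUE`, the effect is applied to female
#'   samples only.
#' @param direction_consistency Fraction of target CpGs whose effect
#'   keeps the sign of `per_allele_effect_beta`; each remaining CpG has
#'   its sign flipped.
#' @param cis_gene_index Optional index of a gene whose expression the
#'   variant drives in cis (placed within the cis window of the variant).
#' @param cis_effect Expression effect per allele for `cis_gene_index`.
#' @param trans_autosomal_cpg_indices Indices of autosomal CpGs affected
#'   in trans (applied in both sexes, as long-range effects are).
#' @param n_ld_proxies Number of LD proxy variants to synthesize at the
#'   following variant indices (positions within 1 Mb of the locus).
#' @param proxy_r2 Target squared dosage correlation of each proxy.
#' @return A `PlantedLocus` list.
#' @export
planted_locus <- function(variant_index, maf = 0.3, target_cpg_indices = integer(),
                          per_allele_effect_beta = -0.01, female_specific = TRUE,
                          direction_consistency = 1, cis_gene_index = NULL,
                          cis_effect = 0, trans_autosomal_cpg_indices = integer(),
                          n_ld_proxies = 0L, proxy_r2 = 0.9) {
  check_range(maf, 0, 0.5, "maf", lo_open = TRUE)
  check_range(abs(per_allele_effect_beta), 0, 0.1, "abs(per_allele_effect_beta)")
  check_range(direction_consistency, 0.5, 1, "direction_consistency")
  structure(list(variant_index = as.integer(variant_index), maf = maf,
                 target_cpg_indices = as.integer(target_cpg_indices),
                 per_allele_effect_beta = per_allele_effect_beta,
                 female_specific = isTRUE(female_specific),
                 direction_consistency = direction_consistency,
                 cis_gene_index = cis_gene_index, cis_effect = cis_effect,
                 trans_autosomal_cpg_indices = as.integer(trans_autosomal_cpg_indices),
                 n_ld_proxies = as.integer(n_ld_proxies), proxy_r2 = proxy_r2),
            class = "PlantedLocus")
}

#' Simulation configuration
#'
#' Defaults describe the package's reference synthetic study: 1,000
#' females and 600 males in 3 cohorts, 2,000 autosomal variants, 500
#' X-chromosomal CpGs with baselines spanning 2.6-55% methylation, 300
#' autosomal CpGs, 50 genes, and 3 latent confounders, on a miniature
#' genome of four 50-Mb autosomes plus a 150-Mb X.
#'
#' @param n_females,n_males Sample counts per sex.
#' @param n_cohorts Number of cohorts (additive cohort intercepts are
#'   planted and later removed by within-cohort normalization).
#' @param n_variants Autosomal variant count.
#' @param n_x_cpgs,n_autosomal_cpgs CpG counts on X / autosomes.
#' @param n_genes Gene count (expression features).
#' @param n_x_variants X-chromosomal variant count (for cis-meQTL
#'   adjustment of X CpGs).
#' @param maf_range MAF range (uniform) for background variants, in
#'   (0, 0.5\].
#' @param baseline_beta_range Range of per-CpG baseline methylation.
#' @param n_latent_factors Number of latent confounders.
#' @param noise_sd Residual SD of methylation on the beta scale.
#' @param cell_effect_sd,latent_effect_sd,cohort_effect_sd SDs of the
#'   per-CpG loadings for cell-count, latent-factor, and cohort
#'   confounding (beta scale).
#' @param expression_noise_sd Residual SD of expression.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param planted_loci List of [planted_locus()] objects.
#' @param chrom_lengths Named vector of chromosome lengths (bp) for the
#'   miniature genome; must include `"X"`.
#' @return A validated `SimulationConfig` list.
#' @export
sim_config <- function(n_females = 1000, n_males = 600, n_cohorts = 3,
                       n_variants = 2000, n_x_cpgs = 500,
                       n_autosomal_cpgs = 300, n_genes = 50,
                       n_x_variants = 100,
                       maf_range = c(0.05, 0.5),
                       baseline_beta_range = c(0.026, 0.55),
                       n_latent_factors = 3, noise_sd = 0.02,
                       cell_effect_sd = 0.004, latent_effect_sd = 0.008,
                       cohort_effect_sd = 0.004,
                       expression_noise_sd = 0.5, seed = 1,
                       planted_loci = list(),
                       chrom_lengths = c("1" = 5e7, "2" = 5e7, "3" = 5e7,
                                         "4" = 5e7, "X" = 1.5e8)) {
  cfg <- list(n_females = n_females, n_males = n_males, n_cohorts = n_cohorts,
              n_variants = n_variants, n_x_cpgs = n_x_cpgs,
              n_autosomal_cpgs = n_autosomal_cpgs, n_genes = n_genes,
              n_x_variants = n_x_variants, maf_range = maf_range,
              baseline_beta_range = baseline_beta_range,
              n_latent_factors = n_latent_factors, noise_sd = noise_sd,
              cell_effect_sd = cell_effect_sd, latent_effect_sd = latent_effect_sd,
              cohort_effect_sd = cohort_effect_sd,
              expression_noise_sd = expression_noise_sd,
              seed = as.integer(seed), planted_loci = planted_loci,
              chrom_lengths = chrom_lengths)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  counts <- c("n_females", "n_cohorts", "n_variants", "n_x_cpgs",
              "n_autosomal_cpgs", "n_genes")
  for (f in counts) if (!is_count(cfg[[f]]) || cfg[[f]] <= 0)
    stopf("config field %s must be a positive count", f)
  if (!is_count(cfg$n_males)) stopf("n_males must be a nonnegative count")
  check_range(cfg$maf_range, 0, 0.5, "maf_range", lo_open = TRUE)
  check_range(cfg$baseline_beta_range, 0, 1, "baseline_beta_range",
              lo_open = TRUE, hi_open = TRUE)
  if (!"X" %in% names(cfg$chrom_lengths)) stopf("chrom_lengths must include 'X'")
  for (pl in cfg$planted_loci) {
    if (!inherits(pl, "PlantedLocus")) stopf("planted_loci must be planted_locus() objects")
    if (pl$variant_index < 1 || pl$variant_index > cfg$n_variants)
      stopf("planted variant_index %d outside 1..%d", pl$variant_index, cfg$n_variants)
    if (length(pl$target_cpg_indices) &&
        (min(pl$target_cpg_indices) < 1 || max(pl$target_cpg_indices) > cfg$n_x_cpgs))
      stopf("planted target CpG indices must lie within the X CpG range 1..%d",
            cfg$n_x_cpgs)
    if (pl$variant_index + pl$n_ld_proxies > cfg$n_variants)
      stopf("LD proxies of variant %d exceed the variant panel", pl$variant_index)
  }
  structure(cfg, class = "SimulationConfig")
}

sample_ids_for <- function(cfg) {
  sprintf("S%05d", seq_len(cfg$n_females + cfg$n_males))
}

autosome_names <- function(cfg) setdiff(names(cfg$chrom_lengths), "X")

## HWE dosages for one variant
draw_dosages <- function(n, maf) stats::rbinom(n, 2L, maf)

## LD proxy: copy the source dosage per sample with probability rho,
## redraw otherwise; dosage correlation equals rho at matched MAF.
draw_proxy <- function(src, maf, r2) {
  rho <- sqrt(r2)
  n <- length(src)
  keep <- stats::runif(n) < rho
  ifelse(keep, src, draw_dosages(n, maf))
}

#' Simulate the autosomal genotype panel
#'
#' Variants are drawn under Hardy-Weinberg proportions at MAFs uniform in
#' `maf_range` (planted loci at their configured MAF), assigned to
#' autosomes of the miniature genome, and annotated with true MAF,
#' empirical exact-HWE P, call rate 1 and info score 1. LD proxies of
#' planted loci occupy the immediately following variant indices at
#' positions within 1 Mb.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  config <- validate_config(config)
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_females + config$n_males
  p <- config$n_variants
  ids <- sample_ids_for(config)
  autos <- autosome_names(config)

  maf <- stats::runif(p, config$maf_range[1L], config$maf_range[2L])
  chrom <- sample(autos, p, replace = TRUE)
  pos <- integer(p)
  for (ch in autos) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(config$chrom_lengths[[ch]] - 2e6, length(idx))) + 1e6
  }

  ## planted loci: fixed MAF, spread over distinct autosomes
  for (k in seq_along(config$planted_loci)) {
    pl <- config$planted_loci[[k]]
    i <- pl$variant_index
    maf[i] <- pl$maf
    chrom[i] <- autos[(k - 1L) %% length(autos) + 1L]
    pos[i] <- round(config$chrom_lengths[[chrom[i]]] / 2) + (k - 1L) * 50000L
    if (pl$n_ld_proxies > 0) {
      prox <- i + seq_len(pl$n_ld_proxies)
      maf[prox] <- pl$maf
      chrom[prox] <- chrom[i]
      pos[prox] <- pos[i] + seq_len(pl$n_ld_proxies) * 10000L
    }
  }

  dos <- matrix(0L, n, p, dimnames = list(ids, sprintf("var%05d", seq_len(p))))
  for (j in seq_len(p)) dos[, j] <- draw_dosages(n, maf[j])
  for (pl in config$planted_loci) {
    if (pl$n_ld_proxies > 0) {
      src <- dos[, pl$variant_index]
      for (d in seq_len(pl$n_ld_proxies))
        dos[, pl$variant_index + d] <- draw_proxy(src, pl$maf, pl$proxy_r2)
    }
  }

  variants <- data.frame(id = colnames(dos), chrom = chrom, pos = pos,
                         ref = "A", alt = "B", maf = maf,
                         call_rate = 1, info = 1, stringsAsFactors = FALSE)
  variants$hwe_p <- vapply(seq_len(p), function(j) {
    g <- dos[, j]
    hwe_exact_test(sum(g == 1L), sum(g == 0L), sum(g == 2L))
  }, numeric(1))
  genotype_matrix(dos + 0, variants)
}

## X-chromosome variant panel (used for cis-meQTL adjustment of X CpGs)
simulate_x_genotypes <- function(config) {
  config <- validate_config(config)
  set.seed(stage_seed(config$seed, 8L))
  n <- config$n_females + config$n_males
  p <- config$n_x_variants
  ids <- sample_ids_for(config)
  maf <- stats::runif(p, config$maf_range[1L], config$maf_range[2L])
  pos <- sort(sample.int(config$chrom_lengths[["X"]] - 2e6, p)) + 1e6
  dos <- matrix(0L, n, p, dimnames = list(ids, sprintf("xvar%04d", seq_len(p))))
  for (j in seq_len(p)) dos[, j] <- draw_dosages(n, maf[j])
  variants <- data.frame(id = colnames(dos), chrom = "X", pos = pos,
                         ref = "A", alt = "B", maf = maf,
                         call_rate = 1, info = 1, hwe_p = 1,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos + 0, variants)
}

#' Simulate per-sample covariates
#'
#' Sex, age, cohort, six strictly positive blood cell counts, a technical
#' batch nested in cohort, and unit-variance latent confounder scores.
#'
#' @param config A [sim_config()].
#' @return A [covariate_bundle()].
#' @export
simulate_covariates <- function(config) {
  config <- validate_config(config)
  set.seed(stage_seed(config$seed, 2L))
  n <- config$n_females + config$n_males
  ids <- sample_ids_for(config)
  sex <- rep(c("female", "male"), c(config$n_females, config$n_males))
  cohort <- paste0("cohort", rep_len(seq_len(config$n_cohorts), n))
  age <- sample(18:80, n, replace = TRUE)
  ## lognormal cell counts: typical whole-blood magnitudes (10^9/L; rbc 10^12/L)
  meanlog <- c(lymphocytes = 0.7, neutrophils = 1.3, monocytes = -0.7,
               eosinophils = -1.6, basophils = -3, rbc = 1.5)
  cells <- vapply(meanlog, function(m) stats::rlnorm(n, m, 0.3), numeric(n))
  batch <- paste0(cohort, "_b", rep_len(1:2, n))
  latent <- NULL
  if (config$n_latent_factors > 0) {
    latent <- matrix(stats::rnorm(n * config$n_latent_factors), n,
                     config$n_latent_factors,
                     dimnames = list(ids, paste0("LF", seq_len(config$n_latent_factors))))
    latent <- scale(latent)  # unit variance per factor
    attr(latent, "scaled:center") <- NULL
    attr(latent, "scaled:scale") <- NULL
  }
  df <- data.frame(sample_id = ids, sex = sex, age = age, cohort = cohort,
                   cells, batch = batch, stringsAsFactors = FALSE)
  covariate_bundle(df, latent = latent)
}

#' Build the ground truth for a configuration
#'
#' Draws the fixed quantities behind the trait simulators: CpG and gene
#' coordinates on the miniature genome, per-CpG baselines, confounder
#' loadings, cohort intercepts, and the realized per-CpG effect signs
#' (each target CpG keeps the planted sign with probability
#' `direction_consistency`).
#'
#' @param config A [sim_config()].
#' @param G The [simulate_genotypes()] output (variant positions anchor
#'   cis gene placement).
#' @return A `GroundTruth` list.
#' @export
ground_truth <- function(config, G) {
  config <- validate_config(config)
  set.seed(stage_seed(config$seed, 3L))
  xlen <- config$chrom_lengths[["X"]]
  autos <- autosome_names(config)

  x_feat <- data.frame(id = sprintf("cgX%05d", seq_len(config$n_x_cpgs)),
                       chrom = "X",
                       start = sort(sample.int(xlen - 2e6, config$n_x_cpgs)) + 1e6,
                       stringsAsFactors = FALSE)
  x_feat$end <- x_feat$start + 1L
  a_chrom <- sample(autos, config$n_autosomal_cpgs, replace = TRUE)
  a_pos <- integer(config$n_autosomal_cpgs)
  for (ch in autos) {
    idx <- which(a_chrom == ch)
    a_pos[idx] <- sort(sample.int(config$chrom_lengths[[ch]] - 2e6, length(idx))) + 1e6
  }
  a_feat <- data.frame(id = sprintf("cgA%05d", seq_len(config$n_autosomal_cpgs)),
                       chrom = a_chrom, start = a_pos, end = a_pos + 1L,
                       stringsAsFactors = FALSE)

  ## genes: planted cis genes inside the cis window of their variant,
  ## the rest placed at random on autosomes
  g_chrom <- sample(autos, config$n_genes, replace = TRUE)
  g_start <- integer(config$n_genes)
  for (ch in autos) {
    idx <- which(g_chrom == ch)
    g_start[idx] <- sample.int(config$chrom_lengths[[ch]] - 2e6, length(idx)) + 1e6
  }
  g_end <- g_start + 20000L
  for (pl in config$planted_loci) {
    gi <- pl$cis_gene_index
    if (!is.null(gi)) {
      vi <- pl$variant_index
      g_chrom[gi] <- G$variants$chrom[vi]
      g_start[gi] <- G$variants$pos[vi] + 50000L
      g_end[gi] <- g_start[gi] + 20000L
    }
  }
  gene_feat <- data.frame(id = sprintf("gene%03d", seq_len(config$n_genes)),
                          chrom = g_chrom, start = g_start, end = g_end,
                          strand = "+", stringsAsFactors = FALSE)

  br <- config$baseline_beta_range
  truth <- list(
    planted_loci = config$planted_loci,
    x_features = x_feat, auto_features = a_feat, gene_features = gene_feat,
    x_baselines = stats::runif(config$n_x_cpgs, br[1L], br[2L]),
    auto_baselines = stats::runif(config$n_autosomal_cpgs, br[1L], br[2L]),
    x_cell_loadings = matrix(stats::rnorm(6 * config$n_x_cpgs, 0, config$cell_effect_sd), 6),
    auto_cell_loadings = matrix(stats::rnorm(6 * config$n_autosomal_cpgs, 0, config$cell_effect_sd), 6),
    x_latent_loadings = matrix(stats::rnorm(config$n_latent_factors * config$n_x_cpgs,
                                            0, config$latent_effect_sd),
                               max(config$n_latent_factors, 0)),
    auto_latent_loadings = matrix(stats::rnorm(config$n_latent_factors * config$n_autosomal_cpgs,
                                               0, config$latent_effect_sd),
                                  max(config$n_latent_factors, 0)),
    x_cohort_intercepts = matrix(stats::rnorm(config$n_cohorts * config$n_x_cpgs,
                                              0, config$cohort_effect_sd), config$n_cohorts),
    auto_cohort_intercepts = matrix(stats::rnorm(config$n_cohorts * config$n_autosomal_cpgs,
                                                 0, config$cohort_effect_sd), config$n_cohorts),
    gene_baselines = stats::rnorm(config$n_genes, 5, 1),
    effect_signs = lapply(config$planted_loci, function(pl) {
      s <- ifelse(stats::runif(length(pl$target_cpg_indices)) < pl$direction_consistency, 1, -1)
      stats::setNames(s, as.character(pl$target_cpg_indices))
    }),
    annotation_assignment = NULL)
  class(truth) <- "GroundTruth"
  truth
}

confound_block <- function(C, cell_loadings, latent_loadings, cohort_intercepts) {
  cc <- scale(as.matrix(C$data[cell_count_names()]))
  out <- cc %*% cell_loadings
  if (ncol(C$latent) > 0 && nrow(latent_loadings) == ncol(C$latent))
    out <- out + C$latent %*% latent_loadings
  coh <- as.integer(factor(C$data$cohort, levels = sort(unique(C$data$cohort))))
  out + cohort_intercepts[coh, , drop = FALSE]
}

#' Simulate methylation beta values
#'
#' Per CpG: baseline + planted per-allele genetic effects (females only
#' for female-specific loci; realized signs from the ground truth) +
#' cell-count, latent-factor and cohort confounding + Gaussian noise,
#' truncated to \[0, 1\].
#'
#' @param G [simulate_genotypes()] output.
#' @param C [simulate_covariates()] output (same samples as `G`).
#' @param truth [ground_truth()] output.
#' @param config The [sim_config()].
#' @param which `"X"` for the X-chromosomal CpG matrix, `"autosomal"`
#'   for the autosomal one (which also receives the planted trans
#'   effects, in both sexes).
#' @return A beta-scale [trait_matrix()].
#' @export
simulate_methylation <- function(G, C, truth, config, which = c("X", "autosomal")) {
  which <- match.arg(which)
  if (!identical(rownames(G$dosages), C$data$sample_id))
    stopf("genotype and covariate samples do not match")
  config <- validate_config(config)
  set.seed(stage_seed(config$seed, if (which == "X") 4L else 5L))
  n <- nrow(G$dosages)
  feat <- if (which == "X") truth$x_features else truth$auto_features
  base <- if (which == "X") truth$x_baselines else truth$auto_baselines
  p <- nrow(feat)

  Y <- matrix(rep(base, each = n), n, p,
              dimnames = list(rownames(G$dosages), feat$id))
  Y <- Y + confound_block(C,
                          if (which == "X") truth$x_cell_loadings else truth$auto_cell_loadings,
                          if (which == "X") truth$x_latent_loadings else truth$auto_latent_loadings,
                          if (which == "X") truth$x_cohort_intercepts else truth$auto_cohort_intercepts)

  female <- C$data$sex == "female"
  for (k in seq_along(truth$planted_loci)) {
    pl <- truth$planted_loci[[k]]
    x <- G$dosages[, pl$variant_index]
    if (which == "X") {
      if (length(pl$target_cpg_indices) == 0) next
      eff <- pl$per_allele_effect_beta * truth$effect_signs[[k]]
      carrier <- if (pl$female_specific) x * female else x
      Y[, pl$target_cpg_indices] <- Y[, pl$target_cpg_indices] +
        outer(carrier, eff)
    } else {
      if (length(pl$trans_autosomal_cpg_indices) == 0) next
      ## trans effects are applied to both sexes
      Y[, pl$trans_autosomal_cpg_indices] <-
        Y[, pl$trans_autosomal_cpg_indices] + pl$per_allele_effect_beta * x
    }
  }
  if (config$noise_sd > 0) Y <- Y + stats::rnorm(n * p, 0, config$noise_sd)
  Y <- pmin(pmax(Y, 0), 1)
  trait_matrix(Y, feat, scale_tag = "beta")
}

#' Simulate gene expression
#'
#' Expression = gene baseline + cis effect x dosage (for planted cis
#' genes) + confounding + Gaussian noise. Planted cis genes must lie
#' within the 250 kb cis window of their variant (guaranteed by
#' [ground_truth()]; violated configurations are an error).
#'
#' @inheritParams simulate_methylation
#' @return An expression-scale [trait_matrix()].
#' @export
simulate_expression <- function(G, C, truth, config) {
  if (!identical(rownames(G$dosages), C$data$sample_id))
    stopf("genotype and covariate samples do not match")
  config <- validate_config(config)
  set.seed(stage_seed(config$seed, 6L))
  n <- nrow(G$dosages)
  feat <- truth$gene_features
  p <- nrow(feat)
  E <- matrix(rep(truth$gene_baselines, each = n), n, p,
              dimnames = list(rownames(G$dosages), feat$id))
  for (pl in truth$planted_loci) {
    gi <- pl$cis_gene_index
    if (is.null(gi)) next
    vi <- pl$variant_index
    d <- interval_distance(G$variants$pos[vi], feat$start[gi], feat$end[gi])
    if (G$variants$chrom[vi] != feat$chrom[gi] || d > 250000)
      stopf("planted cis gene %s lies outside the 250 kb cis window of %s",
            feat$id[gi], G$variants$id[vi])
    E[, gi] <- E[, gi] + pl$cis_effect * G$dosages[, vi]
  }
  ## mild confounding on expression (cell counts + latent factors)
  cc <- scale(as.matrix(C$data[cell_count_names()]))
  E <- E + cc %*% matrix(stats::rnorm(6 * p, 0, 0.05), 6)
  if (ncol(C$latent) > 0)
    E <- E + C$latent %*% matrix(stats::rnorm(ncol(C$latent) * p, 0, 0.1), ncol(C$latent))
  if (config$expression_noise_sd > 0)
    E <- E + stats::rnorm(n * p, 0, config$expression_noise_sd)
  trait_matrix(E, feat, scale_tag = "expression")
}

## distance from a point to an interval (0 if inside), 1-based inclusive
interval_distance <- function(pos, start, end) {
  pmax(0, pmax(start - pos, pos - end))
}

#' Simulate annotation tracks with planted enrichment
#'
#' Builds a CpG-island BED track, a repressive-chromatin track, and a TSS
#' table with X-inactivation classes (escape / variable / subject), such
#' that the planted target CpGs fall in CGI and variable-escape intervals
#' with probability elevated by `enrichment_factor` relative to
#' background CpGs. The recorded annotation assignment is re-derived from
#' the constructed tracks so that it is exactly consistent with what
#' downstream annotation of the tracks yields.
#'
#' @param x_features X CpG coordinate table (`id`, `chrom`, `start`).
#' @param target_cpg_ids Ids of the planted target CpGs.
#' @param enrichment_factor Multiplier (>= 1) on the target CpGs'
#'   membership probability for CGI and variable-escape annotation.
#' @param seed Integer seed.
#' @return List with `annotations` (an [annotation_set()]) and
#'   `assignment` (data frame: `cpg_id`, `cgi_class`, `escape_class`).
#' @export
simulate_annotations <- function(x_features, target_cpg_ids = character(),
                                 enrichment_factor = 4, seed = 1) {
  if (enrichment_factor < 1) stopf("enrichment_factor must be >= 1")
  set.seed(stage_seed(seed, 7L))
  pos <- x_features$start
  n <- nrow(x_features)
  is_target <- x_features$id %in% target_cpg_ids

  p_island <- ifelse(is_target, pmin(0.95, 0.05 * enrichment_factor), 0.05)
  island_cpg <- stats::runif(n) < p_island
  shore_cpg <- !island_cpg & stats::runif(n) < 0.10

  cgi <- data.frame(
    chrom = "X",
    start = c(pos[island_cpg] - 100L, pos[shore_cpg] + 800L),
    end   = c(pos[island_cpg] + 100L, pos[shore_cpg] + 1000L))
  cgi_gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(cgi$chrom, IRanges::IRanges(cgi$start, cgi$end)))

  chrom_mark <- stats::runif(n) < ifelse(is_target, pmin(0.9, 0.3), 0.15)
  mark <- data.frame(chrom = "X", start = pos[chrom_mark] - 200L,
                     end = pos[chrom_mark] + 200L)
  mark_gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(mark$chrom, IRanges::IRanges(mark$start, mark$end)))

  ## TSS classes; 'variable' is the enrichment-carrying class
  p_var <- ifelse(is_target, pmin(0.9, 0.05 * enrichment_factor), 0.05)
  cls <- character(n)
  u <- stats::runif(n)
  rest <- cbind(escape = 0.10, subject = 0.50, none = 0.35)
  for (i in seq_len(n)) {
    pv <- p_var[i]
    w <- rest[1L, ] * (1 - pv) / sum(rest[1L, ])
    cls[i] <- sample(c("variable", names(w)), 1L, prob = c(pv, w))
  }
  has_tss <- cls != "none"
  tss <- data.frame(chrom = "X",
                    pos = pos[has_tss] + sample(c(-1000:-50, 50:1000),
                                                sum(has_tss), replace = TRUE),
                    strand = "+",
                    gene = sprintf("tssgene%05d", which(has_tss)),
                    class = cls[has_tss], stringsAsFactors = FALSE)
  ann <- annotation_set(list(CGI = cgi_gr, H3K27me3 = mark_gr), tss)

  assignment <- data.frame(
    cpg_id = x_features$id,
    cgi_class = annotate_cgi(x_features, ann$tracks$CGI),
    escape_class = annotate_escape(x_features, ann$tss),
    stringsAsFactors = FALSE)
  list(annotations = ann, assignment = assignment)
}

#' Simulate the full study
#'
#' Runs every generator stage and returns the complete synthetic study:
#' autosomal and X genotypes, covariates, X and autosomal methylation,
#' expression, annotation tracks, and the ground truth.
#'
#' @param config A [sim_config()].
#' @param enrichment_factor Annotation enrichment factor for planted
#'   target CpGs.
#' @return List with elements `G`, `G_x`, `C`, `Y_x`, `Y_auto`, `E`,
#'   `annotations`, `truth`, `config`.
#' @export
simulate_study <- function(config, enrichment_factor = 4) {
  config <- validate_config(config)
  G <- simulate_genotypes(config)
  C <- simulate_covariates(config)
  truth <- ground_truth(config, G)
  Y_x <- simulate_methylation(G, C, truth, config, which = "X")
  Y_auto <- simulate_methylation(G, C, truth, config, which = "autosomal")
  E <- simulate_expression(G, C, truth, config)
  G_x <- simulate_x_genotypes(config)
  target_ids <- truth$x_features$id[
    unique(unlist(lapply(truth$planted_loci, `[[`, "target_cpg_indices")))]
  ann <- simulate_annotations(truth$x_features, target_ids,
                              enrichment_factor = enrichment_factor,
                              seed = config$seed)
  truth$annotation_assignment <- ann$assignment
  list(G = G, G_x = G_x, C = C, Y_x = Y_x, Y_auto = Y_auto, E = E,
       annotations = ann$annotations, truth = truth, config = config)
}

#' Simulate an independent replication sample
#'
#' Fresh female samples in `n_cohorts` replication cohorts, genotyped at
#' the same variant panel and measured at the same X CpGs, sharing the
#' discovery ground truth (baselines, loadings, planted effects) but with
#' independent genotype draws, confounder scores and noise.
#'
#' @param config The discovery [sim_config()].
#' @param truth The discovery [ground_truth()].
#' @param n_cohorts,n_per_cohort Replication cohort structure.
#' @param seed Seed for the replication draw (defaults to
#'   `config$seed + 13`).
#' @return List with `G`, `C`, `Y_x` for the replication sample.
#' @export
simulate_replication_set <- function(config, truth, n_cohorts = 3,
                                     n_per_cohort = 500,
                                     seed = config$seed + 13L) {
  config <- validate_config(config)
  if (n_cohorts != config$n_cohorts)
    stopf("replication n_cohorts must equal the discovery n_cohorts (%d)",
          config$n_cohorts)
  rcfg <- config
  rcfg$n_females <- as.integer(n_cohorts * n_per_cohort)
  rcfg$n_males <- 0L
  rcfg$seed <- as.integer(seed)
  rcfg <- validate_config(rcfg)
  G <- simulate_genotypes(rcfg)
  C <- simulate_covariates(rcfg)
  Y_x <- simulate_methylation(G, C, truth, rcfg, which = "X")
  ## relabel samples so replication ids never collide with discovery ids
  new_ids <- sub("^S", "R", rownames(G$dosages))
  rownames(G$dosages) <- new_ids
  rownames(Y_x$values) <- new_ids
  C$data$sample_id <- new_ids
  rownames(C$data) <- new_ids
  if (ncol(C$latent) > 0) rownames(C$latent) <- new_ids else rownames(C$latent) <- new_ids
  list(G = G, C = C, Y_x = Y_x)
}
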