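## End-to-end orchestration: simulate -> preprocess -> scan -> condition
## -> male-validate -> interaction -> per-CpG effects -> replicate ->
## QTL maps -> enrichment -> evaluation, with one master seed, a
## machine-readable manifest, and TSV result tables.

#' Default pipeline configuration
#'
#' All thresholds of the analysis live here: the genome-wide overall-P
#' cutoff 5e-8, the male overall-P exclusion 0.05, the male Wald
#' replication threshold 1.1e-6, the interaction threshold 5.9e-4, FDR
#' 0.05, the QC four-tuple, and the distance windows (250 kb cis, 1 Mb
#' proxy, 5 Mb trans, 10 kb TSS, 2 kb shore).
#'
#' @param sim A [sim_config()]; the default plants two female-specific
#'   loci (one with a cis gene and trans targets) so every stage has
#'   signal to find.
#' @param enrichment_factor Annotation enrichment of planted CpGs.
#' @param latent_q Latent factor count or `"auto"`.
#' @param q_max Search bound for `latent_q = "auto"`.
#' @param replication List: `n_cohorts`, `n_per_cohort`.
#' @param thresholds List of significance thresholds (see above).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(sim = NULL, enrichment_factor = 4,
                            latent_q = "auto", q_max = 10,
                            replication = list(n_cohorts = 3, n_per_cohort = 500),
                            thresholds = list()) {
  if (is.null(sim)) {
    sim <- sim_config(planted_loci = list(
      planted_locus(variant_index = 10L, maf = 0.3,
                    target_cpg_indices = 1:50,
                    per_allele_effect_beta = -0.015,
                    female_specific = TRUE, cis_gene_index = 1L,
                    cis_effect = -0.13,
                    trans_autosomal_cpg_indices = 1:20,
                    n_ld_proxies = 2L, proxy_r2 = 0.9),
      planted_locus(variant_index = 500L, maf = 0.2,
                    target_cpg_indices = 101:130,
                    per_allele_effect_beta = 0.012,
                    female_specific = TRUE)))
  }
  thr <- utils::modifyList(list(
    alpha = 5e-8, male_alpha = 0.05, male_replication_alpha = 1.1e-6,
    interaction_alpha = 5.9e-4, fdr = 0.05,
    qc = unclass(qc_thresholds()), windows = unclass(window_spec())),
    thresholds)
  structure(list(sim = sim, enrichment_factor = enrichment_factor,
                 latent_q = latent_q, q_max = q_max,
                 replication = replication, thresholds = thr),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  loci <- lapply(raw$sim$planted_loci, function(l) do.call(planted_locus, l))
  sim_args <- raw$sim
  sim_args$planted_loci <- loci
  if (!is.null(sim_args$chrom_lengths))
    sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
  sim <- do.call(sim_config, sim_args)
  pipeline_config(sim = sim,
                  enrichment_factor = raw$enrichment_factor %||% 4,
                  latent_q = raw$latent_q %||% "auto",
                  q_max = raw$q_max %||% 10,
                  replication = raw$replication %||% list(n_cohorts = 3, n_per_cohort = 500),
                  thresholds = raw$thresholds %||% list())
}

#' @rdname read_pipeline_config
#' @param config A `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$planted_loci <- lapply(cfg$sim$planted_loci, function(l) {
    l <- unclass(l)
    l[!vapply(l, is.null, logical(1))]
  })
  cfg$sim$chrom_lengths <- as.list(cfg$sim$chrom_lengths)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

## within-stratum preprocessing: within-cohort INT, then latent factors
## estimated from covariate residuals of the transformed traits
prep_stratum <- function(Y, C, latent_q, q_max) {
  Yn <- int_transform(Y, C)
  Yres <- residualize(Yn, C, include_latent = FALSE)
  lf <- estimate_latent_factors(Yres, q = latent_q, q_max = q_max)
  list(Y = Yn, C = set_latent_factors(C, lf), q = ncol(lf))
}

#' Run the full discovery pipeline on a synthetic study
#'
#' Executes every stage in order on data generated from
#' `config$sim`: QC filtering, within-cohort inverse-normal
#' transformation and latent-factor estimation per analysis stratum,
#' the Simes global scan with iterative conditional locus discovery in
#' females, male validation with LD proxies, genotype-by-sex
#' interaction, per-CpG FDR effect lists with direction tests,
#' multi-cohort Stouffer replication, cis-eQTL / trans-meQTL /
#' X cis-meQTL adjustment mapping, annotation enrichment, and
#' evaluation against the planted truth. Result tables are written to
#' `out_dir` together with a JSON manifest of config, seeds, per-stage
#' counts and output hashes.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory.
#' @param seed Master seed (overrides `config$sim$seed`).
#' @param resume If `TRUE` and an identical run (same config hash and
#'   seed) already completed in `out_dir` with intact outputs, skip
#'   recomputation.
#' @return Invisibly, a list with the manifest, all result tables, and
#'   the in-memory objects (`study`, `loci`, ...).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL,
                         resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- md5_of(list(config = unclass(config), seed = config$sim$seed))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    files <- file.path(out_dir, names(prev$output_hashes))
    if (identical(prev$config_hash, cfg_hash) && all(file.exists(files)) &&
        identical(unname(unlist(prev$output_hashes)),
                  unname(tools::md5sum(files)))) {
      message("run_pipeline: inputs unchanged, reusing completed run")
      return(invisible(list(manifest = prev, tables = read_results(out_dir))))
    }
  }
  thr <- config$thresholds
  windows <- do.call(window_spec, thr$windows)
  message(sprintf(paste0(
    "thresholds: alpha=%g male_alpha=%g male_replication_alpha=%g ",
    "interaction_alpha=%g fdr=%g qc(info>=%g hwe>=%g cr>=%g maf>=%g) ",
    "windows(cis=%g proxy=%g trans=%g tss=%g)"),
    thr$alpha, thr$male_alpha, thr$male_replication_alpha,
    thr$interaction_alpha, thr$fdr, thr$qc$info_min, thr$qc$hwe_p_min,
    thr$qc$call_rate_min, thr$qc$maf_min, windows$cis_window,
    windows$proxy_window, windows$trans_min_distance,
    windows$escape_tss_max_distance))

  ## -- stage 1: simulate ------------------------------------------------
  study <- simulate_study(config$sim, enrichment_factor = config$enrichment_factor)
  truth <- study$truth

  ## -- stage 2: preprocess ----------------------------------------------
  G <- impute_missing_dosages(filter_variants(study$G, do.call(qc_thresholds, thr$qc)))
  message(sprintf("QC: removed %s variants (info/hwe/callrate/maf), kept %d",
                  paste(attr(G, "removed"), collapse = "/"), ncol(G$dosages)))
  female <- study$C$data$sample_id[study$C$data$sex == "female"]
  male <- study$C$data$sample_id[study$C$data$sex == "male"]
  G_f <- subset_samples(G, female);  G_m <- subset_samples(G, male)
  C_f0 <- subset_samples(study$C, female); C_m0 <- subset_samples(study$C, male)
  Yx_f0 <- subset_samples(study$Y_x, female); Yx_m0 <- subset_samples(study$Y_x, male)
  pf <- prep_stratum(Yx_f0, C_f0, config$latent_q, config$q_max)
  pm <- if (length(male)) prep_stratum(Yx_m0, C_m0, config$latent_q, config$q_max) else NULL
  pc <- prep_stratum(study$Y_x, study$C, config$latent_q, config$q_max)
  message(sprintf("latent factors chosen: females=%d males=%s combined=%d",
                  pf$q, if (is.null(pm)) "-" else pm$q, pc$q))

  ## -- stage 3: discovery scan + conditional loci -----------------------
  scan_res <- global_scan(G_f, pf$Y, pf$C, alpha = thr$alpha)
  loci <- conditional_scan(G_f, pf$Y, pf$C, alpha = thr$alpha)
  message(sprintf("discovery: %d significant variants, %d independent loci",
                  length(scan_res$significant), nrow(loci)))

  ## -- stage 4: male validation -----------------------------------------
  maleval <- if (!is.null(pm) && nrow(loci))
    male_validation(loci, G_m, pm$Y, pm$C,
                    proxy_window = windows$proxy_window,
                    male_alpha = thr$male_alpha,
                    male_replication_alpha = thr$male_replication_alpha)
  else data.frame()

  ## -- stage 5: genotype-by-sex interaction ------------------------------
  inter <- if (nrow(loci)) do.call(rbind, lapply(loci$sentinel_variant_id, function(sid) {
    it <- interaction_test(G$dosages[, sid], pc$Y, pc$C)
    data.frame(sentinel_variant_id = sid, interaction_overall_p = it$overall_p,
               significant = it$overall_p < thr$interaction_alpha,
               stringsAsFactors = FALSE)
  })) else data.frame()

  ## -- stage 6: per-CpG effect lists (females, beta-scale reporting) -----
  cpg_eff <- list(); directions <- list()
  for (sid in loci$sentinel_variant_id) {
    pe <- per_cpg_effects(G_f$dosages[, sid], pf$Y, Yx_f0, pf$C, fdr = thr$fdr)
    eff <- pe$effects
    eff$sentinel_variant_id <- sid
    cpg_eff[[sid]] <- eff
    directions[[sid]] <- data.frame(
      sentinel_variant_id = sid, n_pos = pe$direction$n_pos,
      n_neg = pe$direction$n_neg, consistency = pe$direction$consistency,
      sign_test_p = pe$direction$sign_test_p, stringsAsFactors = FALSE)
  }
  cpg_eff_tab <- if (length(cpg_eff)) do.call(rbind, c(cpg_eff, list(make.row.names = FALSE))) else data.frame()
  dir_tab <- if (length(directions)) do.call(rbind, c(directions, list(make.row.names = FALSE))) else data.frame()

  ## -- stage 7: replication ----------------------------------------------
  fs_ids <- if (nrow(maleval)) maleval$sentinel_variant_id[maleval$female_specific] else character(0)
  rep_summary <- data.frame(); rep_meta <- data.frame()
  if (length(fs_ids)) {
    rs <- simulate_replication_set(config$sim, truth,
                                   n_cohorts = config$replication$n_cohorts,
                                   n_per_cohort = config$replication$n_per_cohort)
    Yr <- int_transform(rs$Y_x, rs$C)
    rr <- replicate_sentinels(fs_ids, rs$G, Yr, rs$C)
    rep_summary <- rr$summary; rep_meta <- rr$meta
    message(sprintf("replication: %d/%d sentinels at adjusted P < 0.05",
                    sum(rep_summary$adjusted_p < 0.05), nrow(rep_summary)))
  }

  ## -- stage 8: QTL maps -------------------------------------------------
  E_n <- int_transform(study$E, study$C)
  Yauto_n <- int_transform(study$Y_auto, study$C)
  Gx_n <- study$G_x
  eqtl <- list(); trans <- list(); cisx <- list(); adjtab <- list()
  for (sid in loci$sentinel_variant_id) {
    eq <- tryCatch(cis_eqtl(sid, G, subset_samples(E_n, sample_ids(pc$C)), pc$C,
                            windows = windows),
                   warning = function(w) data.frame())
    if (nrow(eq)) { eq$sentinel_variant_id <- sid; eqtl[[sid]] <- eq }
    tr <- trans_meqtl(sid, G, Yauto_n, pc$C, windows = windows, fdr = thr$fdr)
    tr$sentinel_variant_id <- sid
    trans[[sid]] <- tr
    sig_cpgs <- cpg_eff_tab$feature_id[cpg_eff_tab$sentinel_variant_id == sid &
                                         cpg_eff_tab$significant]
    if (length(sig_cpgs)) {
      sig_cpgs <- utils::head(sig_cpgs, 20L)  # strongest-cis adjustment probe set
      cx <- cis_meqtl_x(sig_cpgs, Gx_n, pc$Y, pc$C, windows = windows)
      cx$sentinel_variant_id <- sid
      cisx[[sid]] <- cx
      adj <- do.call(rbind, lapply(seq_len(nrow(cx)), function(i)
        adjusted_trans_effect(sid, cx$cpg_id[i], cx$cis_snp_id[i],
                              G, Gx_n, pc$Y, pc$C)))
      adjtab[[sid]] <- adj
    }
  }
  eqtl_tab <- if (length(eqtl)) do.call(rbind, c(eqtl, list(make.row.names = FALSE))) else data.frame()
  trans_tab <- if (length(trans)) do.call(rbind, c(trans, list(make.row.names = FALSE))) else data.frame()
  cisx_tab <- if (length(cisx)) do.call(rbind, c(cisx, list(make.row.names = FALSE))) else data.frame()
  adj_tab <- if (length(adjtab)) do.call(rbind, c(adjtab, list(make.row.names = FALSE))) else data.frame()

  ## -- stage 9: enrichment ----------------------------------------------
  enr <- list()
  for (sid in loci$sentinel_variant_id) {
    tgt <- cpg_eff_tab$feature_id[cpg_eff_tab$sentinel_variant_id == sid &
                                    cpg_eff_tab$significant]
    if (length(tgt) == 0L) next
    er <- enrichment_panel(tgt, truth$x_features, study$annotations)
    er$sentinel_variant_id <- sid
    enr[[sid]] <- er
  }
  enr_tab <- if (length(enr)) do.call(rbind, c(enr, list(make.row.names = FALSE))) else data.frame()

  ## -- stage 10: evaluation + manifest -----------------------------------
  run <- list(scan_records = scan_res$records, loci = loci,
              male_validation = maleval, interaction = inter,
              cpg_effects = cpg_eff_tab, direction_tests = dir_tab,
              replication_summary = rep_summary, replication_meta = rep_meta,
              cis_eqtl = eqtl_tab, trans_meqtl = trans_tab,
              cis_meqtl_x = cisx_tab, adjusted_trans = adj_tab,
              enrichment = enr_tab)
  metrics <- evaluate_against_truth(run, truth, G = study$G)
  run$metrics <- metrics

  tables <- Filter(function(x) is.data.frame(x) && nrow(x) > 0, run)
  write_results(tables, out_dir)
  files <- file.path(out_dir, paste0(names(tables), ".tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("xscan")),
    r_version = as.character(getRversion()),
    seed = config$sim$seed,
    config_hash = cfg_hash,
    thresholds = thr,
    counts = list(variants_tested = ncol(G$dosages),
                  loci_found = nrow(loci),
                  female_specific = length(fs_ids),
                  cpgs_at_fdr = sum(cpg_eff_tab$significant %in% TRUE),
                  enrichment_rows = nrow(enr_tab)),
    output_hashes = as.list(stats::setNames(unname(tools::md5sum(files)),
                                            basename(files))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(list(manifest = manifest, study = study, truth = truth,
                   config = config), run))
}

#' Evaluate pipeline results against the planted truth
#'
#' A discovered locus counts as a true positive when its sentinel is the
#' planted variant itself or has dosage r-squared >= 0.8 with it.
#' Reports locus recall and precision, CpG-level recall and empirical
#' FDR over the matched loci's significant CpG lists, sign accuracy of
#' the reported beta-scale effects, and the female-specificity confusion
#' matrix.
#'
#' @param run Result list of [run_pipeline()] (or any list with `loci`,
#'   `cpg_effects`, `male_validation` tables).
#' @param truth The [ground_truth()] the data were generated from.
#' @param G Discovery [genotype_matrix()] (for the proxy r-squared
#'   rule); omit to match on exact variant ids only.
#' @return Data frame of metrics (`metric`, `value`); undefined metrics
#'   (e.g. precision with no discoveries) are `NA`.
#' @export
evaluate_against_truth <- function(run, truth, G = NULL) {
  if (is.null(truth)) stopf("ground truth is required")
  loci <- run$loci
  planted_idx <- vapply(truth$planted_loci, `[[`, integer(1), "variant_index")
  planted_ids <- sprintf("var%05d", planted_idx)
  matched_planted <- rep(NA_character_, if (is.null(loci)) 0 else nrow(loci))
  if (!is.null(loci) && nrow(loci)) {
    for (i in seq_len(nrow(loci))) {
      sid <- loci$sentinel_variant_id[i]
      if (sid %in% planted_ids) { matched_planted[i] <- sid; next }
      if (!is.null(G) && sid %in% colnames(G$dosages)) {
        r2 <- vapply(planted_ids, function(pid)
          if (pid %in% colnames(G$dosages))
            stats::cor(G$dosages[, sid], G$dosages[, pid])^2 else 0, numeric(1))
        if (any(r2 >= 0.8)) matched_planted[i] <- planted_ids[which.max(r2)]
      }
    }
  }
  n_disc <- length(matched_planted)
  tp_loci <- unique(matched_planted[!is.na(matched_planted)])
  recall <- length(tp_loci) / length(planted_ids)
  precision <- if (n_disc > 0) sum(!is.na(matched_planted)) / n_disc else NA_real_

  ## CpG-level metrics over matched loci
  cpg_recall <- cpg_fdr <- sign_acc <- NA_real_
  eff <- run$cpg_effects
  if (!is.null(eff) && nrow(eff)) {
    hits <- misses <- 0L; false_pos <- 0L; sign_ok <- sign_tot <- 0L
    for (i in which(!is.na(matched_planted))) {
      k <- match(matched_planted[i], planted_ids)
      pl <- truth$planted_loci[[k]]
      target_ids <- truth$x_features$id[pl$target_cpg_indices]
      sig <- eff$feature_id[eff$sentinel_variant_id == loci$sentinel_variant_id[i] &
                              eff$significant]
      hits <- hits + length(intersect(sig, target_ids))
      misses <- misses + length(setdiff(target_ids, sig))
      false_pos <- false_pos + length(setdiff(sig, target_ids))
      tp_cpgs <- intersect(sig, target_ids)
      if (length(tp_cpgs)) {
        realized <- sign(pl$per_allele_effect_beta) *
          truth$effect_signs[[k]][as.character(pl$target_cpg_indices)]
        names(realized) <- target_ids
        est <- eff$beta_raw[match(tp_cpgs, eff$feature_id)]
        est_sign <- sign(eff$beta_raw[eff$sentinel_variant_id == loci$sentinel_variant_id[i]][
          match(tp_cpgs, eff$feature_id[eff$sentinel_variant_id == loci$sentinel_variant_id[i]])])
        sign_ok <- sign_ok + sum(est_sign == realized[tp_cpgs])
        sign_tot <- sign_tot + length(tp_cpgs)
      }
    }
    if (hits + misses > 0) cpg_recall <- hits / (hits + misses)
    if (hits + false_pos > 0) cpg_fdr <- false_pos / (hits + false_pos)
    if (sign_tot > 0) sign_acc <- sign_ok / sign_tot
  }

  ## female-specificity confusion
  fs_tp <- fs_fp <- fs_fn <- fs_tn <- NA_real_
  mv <- run$male_validation
  if (!is.null(mv) && nrow(mv)) {
    idx <- match(mv$sentinel_variant_id, loci$sentinel_variant_id)
    truth_fs <- vapply(matched_planted[idx], function(m)
      if (is.na(m)) NA else truth$planted_loci[[match(m, planted_ids)]]$female_specific,
      logical(1))
    ok <- !is.na(truth_fs)
    fs_tp <- sum(mv$female_specific[ok] & truth_fs[ok])
    fs_fp <- sum(mv$female_specific[ok] & !truth_fs[ok])
    fs_fn <- sum(!mv$female_specific[ok] & truth_fs[ok])
    fs_tn <- sum(!mv$female_specific[ok] & !truth_fs[ok])
  }
  data.frame(metric = c("locus_recall", "locus_precision", "cpg_recall",
                        "cpg_empirical_fdr", "sign_accuracy",
                        "female_specific_tp", "female_specific_fp",
                        "female_specific_fn", "female_specific_tn"),
             value = c(recall, precision, cpg_recall, cpg_fdr, sign_acc,
                       fs_tp, fs_fp, fs_fn, fs_tn),
             stringsAsFactors = FALSE)
}
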