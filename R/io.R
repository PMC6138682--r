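## File formats. Internal coordinates are 1-based inclusive everywhere
## (VCF / array-manifest convention); BED stays 0-based half-open on disk,
## with rtracklayer owning the conversion at this single boundary.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a genotype dosage matrix
#'
#' @param path Path to a VCF (dosages in the `DS` FORMAT field) or to a
#'   TSV dosage matrix (rows = samples, first column `sample_id`, one
#'   column per variant).
#' @param format `"vcf"` or `"tsv"`.
#' @param variants_path For `format = "tsv"`, path to the per-variant
#'   metadata TSV (columns `id`, `chrom`, `pos`, and optionally `ref`,
#'   `alt`, `maf`, `hwe_p`, `call_rate`, `info`). For VCF the metadata is
#'   carried in INFO fields and this argument is ignored.
#' @return A [genotype_matrix()]. Missing dosages are kept as `NA` and
#'   their count reported; MAF/call rate/HWE are recomputed when absent.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), variants_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (is.null(ds)) stopf("VCF has no DS genotype field: %s", path)
    dosages <- t(ds)
    colnames(dosages) <- fix$ID
    variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                           pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT,
                           stringsAsFactors = FALSE)
    for (f in c("MAF", "HWEP", "CR", "RSQ")) {
      val <- suppressWarnings(vcfR::extract.info(v, element = f, as.numeric = TRUE))
      if (!is.null(val) && !all(is.na(val)))
        variants[[c(MAF = "maf", HWEP = "hwe_p", CR = "call_rate", RSQ = "info")[f]]] <- val
    }
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1L] != "sample_id")
      stopf("dosage TSV must have 'sample_id' as its first column: %s", path)
    dosages <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(dosages) <- tab$sample_id
    if (is.null(variants_path))
      stopf("variants_path is required for TSV genotypes")
    variants <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    if (!identical(as.character(variants$id), colnames(dosages)))
      stopf("variant metadata does not match dosage columns in %s", path)
  }
  n_missing <- sum(is.na(dosages))
  if (n_missing > 0)
    message(sprintf("read_genotypes: %d missing dosage values flagged", n_missing))
  genotype_matrix(dosages, variants)
}

#' Write genotypes to VCF (DS field) or TSV
#'
#' @param G A [genotype_matrix()].
#' @param path Output path. For `format = "tsv"` the variant metadata is
#'   written alongside (`variants_path`, default `<path>.variants.tsv`).
#' @param format `"vcf"` or `"tsv"`.
#' @param variants_path Metadata path for TSV output.
#' @export
write_genotypes <- function(G, path, format = c("tsv", "vcf"),
                            variants_path = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    va <- G$variants
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
             "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
             "##INFO=<ID=HWEP,Number=1,Type=Float,Description=\"Exact HWE P-value\">",
             "##INFO=<ID=CR,Number=1,Type=Float,Description=\"Call rate\">",
             "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation info score\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G$dosages)), collapse = "\t"))
    body <- vapply(seq_len(nrow(va)), function(i) {
      ds <- fmt_num(G$dosages[, i])
      ds[ds == "NA"] <- "."
      paste(c(va$chrom[i], va$pos[i], va$id[i], va$ref[i], va$alt[i], ".", "PASS",
              sprintf("MAF=%s;HWEP=%s;CR=%s;RSQ=%s", fmt_num(va$maf[i]),
                      fmt_num(va$hwe_p[i]), fmt_num(va$call_rate[i]),
                      fmt_num(va$info[i])),
              "DS", ds), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, body), path)
  } else {
    write_matrix_tsv(G$dosages, path)
    variants_path <- variants_path %||% paste0(path, ".variants.tsv")
    write_table_tsv(G$variants, variants_path)
  }
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_tsv(df, path)
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait matrix (methylation or expression)
#'
#' @param path TSV with rows = samples, first column `sample_id`.
#' @param features_path TSV of feature coordinates (`id`, `chrom`,
#'   `start`, `end`, optional `strand`), 1-based inclusive.
#' @param scale_tag `"beta"`, `"normalized"` or `"expression"`; beta
#'   values are validated to lie in \[0, 1\].
#' @return A [trait_matrix()].
#' @export
read_traits <- function(path, features_path, scale_tag = "beta") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "sample_id")
    stopf("trait TSV must have 'sample_id' as its first column: %s", path)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$sample_id
  features <- utils::read.table(features_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  trait_matrix(values, features, scale_tag = scale_tag)
}

#' @rdname read_traits
#' @param Y A [trait_matrix()] to write.
#' @export
write_traits <- function(Y, path, features_path) {
  write_matrix_tsv(Y$values, path)
  write_table_tsv(Y$features, features_path)
  invisible(path)
}

#' Read / write per-sample covariates
#'
#' One TSV holding sex, age, cohort, the six cell counts and batch;
#' latent factor scores, when present, are stored as columns named
#' `LF1`, `LF2`, ...
#'
#' @param path Covariate TSV path.
#' @return A [covariate_bundle()].
#' @export
read_covariates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lf_cols <- grep("^LF[0-9]+$", names(tab), value = TRUE)
  latent <- NULL
  if (length(lf_cols)) {
    latent <- as.matrix(tab[lf_cols])
    rownames(latent) <- tab$sample_id
  }
  covariate_bundle(tab[setdiff(names(tab), lf_cols)], latent = latent)
}

#' @rdname read_covariates
#' @param C A [covariate_bundle()].
#' @export
write_covariates <- function(C, path) {
  df <- C$data
  if (ncol(C$latent) > 0) {
    lf <- as.data.frame(C$latent)
    names(lf) <- paste0("LF", seq_len(ncol(lf)))
    df <- cbind(df, lf)
  }
  write_table_tsv(df, path)
}

#' Read annotation tracks and the TSS escape table
#'
#' @param bed_paths Named character vector of BED file paths (0-based
#'   half-open on disk; converted to 1-based inclusive internally).
#' @param tss_path TSV with columns `chrom`, `pos`, `strand`, `gene`,
#'   `class`.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(bed_paths, tss_path) {
  if (is.null(names(bed_paths))) stopf("bed_paths must be named by track")
  tracks <- lapply(bed_paths, function(p) rtracklayer::import(p, format = "BED"))
  tss <- utils::read.table(tss_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  annotation_set(tracks, tss)
}

#' @rdname read_annotations
#' @param A An [annotation_set()].
#' @param dir Output directory; one `<track>.bed` per track plus
#'   `tss.tsv`.
#' @export
write_annotations <- function(A, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(A$tracks)) {
    tr <- A$tracks[[nm]]
    S4Vectors::mcols(tr) <- NULL
    rtracklayer::export(tr, file.path(dir, paste0(nm, ".bed")), format = "BED")
  }
  write_table_tsv(A$tss, file.path(dir, "tss.tsv"))
  invisible(dir)
}

#' Write / read result tables
#'
#' @param tables Named list of data frames.
#' @param dir Output directory; each table goes to `<name>.tsv` with a
#'   deterministic column order and full numeric precision.
#' @export
write_results <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) write_table_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}

#' @rdname write_results
#' @export
read_results <- function(dir) {
  paths <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(paths, utils::read.table, header = TRUE, sep = "\t",
                stringsAsFactors = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(paths))
  out
}

#' Write a complete simulated study to disk
#'
#' Genotypes (VCF with DS field plus a TSV mirror), X and autosomal
#' methylation, expression, covariates, annotation tracks, and a JSON
#' ground-truth sidecar (planted loci, realized per-CpG signs,
#' annotation assignment).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(study$G, file.path(dir, "genotypes.vcf"), format = "vcf")
  write_genotypes(study$G_x, file.path(dir, "genotypes_x.vcf"), format = "vcf")
  write_traits(study$Y_x, file.path(dir, "methylation_x.tsv"),
               file.path(dir, "cpgs_x.tsv"))
  write_traits(study$Y_auto, file.path(dir, "methylation_auto.tsv"),
               file.path(dir, "cpgs_auto.tsv"))
  write_traits(study$E, file.path(dir, "expression.tsv"),
               file.path(dir, "genes.tsv"))
  write_covariates(study$C, file.path(dir, "covariates.tsv"))
  write_annotations(study$annotations, file.path(dir, "annotations"))
  truth <- study$truth
  sidecar <- list(
    planted_loci = lapply(seq_along(truth$planted_loci), function(k) {
      pl <- unclass(truth$planted_loci[[k]])
      pl$target_cpg_ids <- truth$x_features$id[pl$target_cpg_indices]
      pl$realized_signs <- unname(truth$effect_signs[[k]])
      pl[!vapply(pl, is.null, logical(1))]
    }),
    annotation_assignment = truth$annotation_assignment)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
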