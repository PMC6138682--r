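## Core data containers. Plain S3 around matrices + metadata data.frames,
## the shape used by matrix-QTL style tools: samples are rows everywhere,
## sample ids are rownames, feature/variant ids are colnames.

#' Genotype dosage matrix with per-variant metadata
#'
#' Container for imputed genotype dosages (0..2 copies of the alternative
#' allele) together with the per-variant QC metadata the pipeline filters
#' on (MAF, exact Hardy-Weinberg P, call rate, imputation info score).
#'
#' @param dosages Numeric matrix, samples x variants, values in \[0, 2\] or
#'   `NA` for missing. Rownames are sample ids, colnames variant ids.
#' @param variants Data frame with one row per variant. Required columns:
#'   `id`, `chrom`, `pos` (1-based). Optional: `ref`, `alt`, `maf`,
#'   `hwe_p`, `call_rate`, `info`; missing ones are computed from the
#'   dosages (`maf`, `call_rate`, `hwe_p` from rounded hard calls) or
#'   defaulted (`info = 1`).
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosages` and `variants`.
#' @export
genotype_matrix <- function(dosages, variants) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stopf("dosages must be a numeric matrix (samples x variants)")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stopf("dosages must carry sample ids as rownames and variant ids as colnames")
  if (anyDuplicated(rownames(dosages)))
    stopf("duplicated sample id in genotypes: '%s'",
          rownames(dosages)[duplicated(rownames(dosages))][1L])
  if (anyDuplicated(colnames(dosages)))
    stopf("duplicated variant id in genotypes: '%s'",
          colnames(dosages)[duplicated(colnames(dosages))][1L])
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2)
    stopf("dosage values must lie in [0, 2]; found %g", if (rng[1L] < 0) rng[1L] else rng[2L])
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(variants)))
    stopf("variant metadata must contain columns: %s", paste(need, collapse = ", "))
  if (!identical(as.character(variants$id), colnames(dosages)))
    stopf("variant metadata ids must match dosage colnames in order")
  if (any(variants$pos <= 0)) stopf("variant positions must be strictly positive")

  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "B"
  if (is.null(variants$maf)) {
    af <- colMeans(dosages, na.rm = TRUE) / 2
    variants$maf <- pmin(af, 1 - af)
  }
  if (is.null(variants$call_rate)) variants$call_rate <- colMeans(!is.na(dosages))
  if (is.null(variants$hwe_p)) {
    hard <- round(dosages)
    variants$hwe_p <- apply(hard, 2L, function(g) {
      g <- g[!is.na(g)]
      hwe_exact_test(sum(g == 1), sum(g == 0), sum(g == 2))
    })
  }
  if (is.null(variants$info)) variants$info <- 1
  structure(list(dosages = dosages, variants = variants),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (chrom: %s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

#' Trait matrix (methylation or expression) with feature coordinates
#'
#' @param values Numeric matrix, samples x features; rownames sample ids,
#'   colnames feature ids.
#' @param features Data frame with columns `id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and optional `strand`.
#' @param scale_tag One of `"beta"` (methylation fractions, checked to lie
#'   in \[0,1\]), `"normalized"` (after inverse-normal transformation), or
#'   `"expression"`.
#' @return Object of class `TraitMatrix`.
#' @export
trait_matrix <- function(values, features,
                         scale_tag = c("beta", "normalized", "expression")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must carry sample ids as rownames and feature ids as colnames")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end")
  if (!all(need %in% names(features)))
    stopf("feature metadata must contain columns: %s", paste(need, collapse = ", "))
  if (!identical(as.character(features$id), colnames(values)))
    stopf("feature metadata ids must match value colnames in order")
  if (is.null(features$strand)) features$strand <- "*"
  if (scale_tag == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1)
      stopf("beta-scale trait values must lie in [0, 1]; found %g",
            if (rng[1L] < 0) rng[1L] else rng[2L])
  }
  structure(list(values = values, features = features, scale_tag = scale_tag),
            class = "TraitMatrix")
}

#' @export
print.TraitMatrix <- function(x, ...) {
  cat(sprintf("TraitMatrix [%s]: %d samples x %d features\n",
              x$scale_tag, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.TraitMatrix <- function(x) dim(x$values)

#' Per-sample covariates plus latent factors
#'
#' Known covariates (sex, age, cohort, six blood cell counts, technical
#' batch) and an optional matrix of estimated latent factor scores.
#'
#' @param data Data frame with columns `sample_id`, `sex`
#'   ("female"/"male"), `age`, `cohort`, the six cell counts
#'   (`lymphocytes`, `neutrophils`, `monocytes`, `eosinophils`,
#'   `basophils`, `rbc`), and `batch`. No missing values are allowed.
#' @param latent Optional numeric matrix of latent factor scores,
#'   samples x q, rownames matching `sample_id`. `NULL` means no factors.
#' @return Object of class `CovariateBundle`.
#' @export
covariate_bundle <- function(data, latent = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "age", "cohort", cell_count_names(), "batch")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("covariates missing columns: %s", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stopf("covariates contain missing values; complete rows required")
  if (anyDuplicated(data$sample_id)) stopf("duplicated sample id in covariates")
  if (!all(data$sex %in% c("female", "male")))
    stopf("sex must be 'female' or 'male'")
  cc <- as.matrix(data[cell_count_names()])
  if (any(cc < 0)) stopf("cell counts must be nonnegative")
  if (is.null(latent)) {
    latent <- matrix(numeric(0), nrow = nrow(data), ncol = 0,
                     dimnames = list(data$sample_id, NULL))
  } else {
    latent <- as.matrix(latent)
    if (nrow(latent) != nrow(data))
      stopf("latent factor matrix must have one row per sample")
    if (is.null(rownames(latent))) rownames(latent) <- data$sample_id
    if (!identical(rownames(latent), data$sample_id))
      stopf("latent factor rownames must match sample_id order")
    if (ncol(latent) > 0 && is.null(colnames(latent)))
      colnames(latent) <- paste0("LF", seq_len(ncol(latent)))
  }
  rownames(data) <- data$sample_id
  structure(list(data = data, latent = latent), class = "CovariateBundle")
}

cell_count_names <- function() {
  c("lymphocytes", "neutrophils", "monocytes", "eosinophils", "basophils", "rbc")
}

#' @export
print.CovariateBundle <- function(x, ...) {
  cat(sprintf("CovariateBundle: %d samples (%d female, %d male), %d cohorts, %d latent factors\n",
              nrow(x$data), sum(x$data$sex == "female"), sum(x$data$sex == "male"),
              length(unique(x$data$cohort)), ncol(x$latent)))
  invisible(x)
}

#' Annotation tracks and TSS escape table
#'
#' @param tracks Named list of interval tracks, each a `GRanges` (or a
#'   data frame with `chrom`, `start`, `end`, 1-based inclusive, which is
#'   converted). Tracks are sorted on construction.
#' @param tss Data frame with columns `chrom`, `pos`, `gene`, `class`
#'   (one of "escape", "variable", "subject") and optional `strand`,
#'   giving the X-inactivation status of each transcription start site.
#' @return Object of class `AnnotationSet`.
#' @export
annotation_set <- function(tracks, tss) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stopf("tracks must be a named list")
  tracks <- lapply(tracks, function(tr) {
    if (is.data.frame(tr)) {
      tr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
    }
    if (!methods::is(tr, "GRanges")) stopf("each track must be a GRanges or data frame")
    if (any(BiocGenerics::width(tr) < 1)) stopf("track intervals must have positive length")
    BiocGenerics::sort(tr)
  })
  tss <- as.data.frame(tss, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gene", "class")
  if (!all(need %in% names(tss)))
    stopf("tss table must contain columns: %s", paste(need, collapse = ", "))
  if (!all(tss$class %in% c("escape", "variable", "subject")))
    stopf("tss class must be one of escape/variable/subject")
  if (is.null(tss$strand)) tss$strand <- "*"
  tss <- tss[order(tss$chrom, tss$pos), , drop = FALSE]
  rownames(tss) <- NULL
  structure(list(tracks = tracks, tss = tss), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d tracks (%s), %d TSS records\n",
              length(x$tracks), paste(names(x$tracks), collapse = ", "),
              nrow(x$tss)))
  invisible(x)
}

## ---- sample subsetting / alignment ------------------------------------

sample_ids <- function(x) {
  switch(class(x)[1L],
         GenotypeMatrix  = rownames(x$dosages),
         TraitMatrix     = rownames(x$values),
         CovariateBundle = x$data$sample_id,
         stopf("unsupported object of class %s", class(x)[1L]))
}

subset_samples <- function(x, ids) {
  switch(class(x)[1L],
    GenotypeMatrix = {
      x$dosages <- x$dosages[ids, , drop = FALSE]
      x
    },
    TraitMatrix = {
      x$values <- x$values[ids, , drop = FALSE]
      x
    },
    CovariateBundle = {
      x$data <- x$data[ids, , drop = FALSE]
      x$latent <- x$latent[ids, , drop = FALSE]
      x
    },
    stopf("unsupported object of class %s", class(x)[1L]))
}

#' Align objects on their shared samples
#'
#' Intersects the sample ids of all supplied objects (genotypes, traits,
#' covariates) and returns each restricted to the common samples, in the
#' row order of the first object. The number of samples dropped from each
#' input is reported via `message()`.
#'
#' @param ... Named `GenotypeMatrix` / `TraitMatrix` / `CovariateBundle`
#'   objects.
#' @return Named list of the aligned objects, with attribute `n_dropped`.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  if (length(objs) < 2L) stopf("need at least two objects to align")
  ids <- lapply(objs, sample_ids)
  common <- Reduce(intersect, ids)
  if (length(common) == 0L) stopf("no samples shared between inputs")
  common <- ids[[1L]][ids[[1L]] %in% common]  # order-stable on first object
  dropped <- vapply(ids, function(v) length(v) - length(common), integer(1))
  if (any(dropped > 0))
    message(sprintf("align_samples: dropped %s samples (kept %d)",
                    paste(dropped, collapse = "/"), length(common)))
  out <- lapply(objs, subset_samples, ids = common)
  attr(out, "n_dropped") <- dropped
  out
}
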