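## CpG annotation (CpG-island / shore classes, interval-track overlap,
## X-inactivation escape class via the nearest TSS) and Fisher's exact
## enrichment of an associated CpG set against the chromosome-wide
## background.

cpg_granges <- function(features) {
  GenomicRanges::GRanges(features$chrom,
                         IRanges::IRanges(features$start, features$start))
}

#' Classify CpGs as island / shore / non-CGI
#'
#' Island if the CpG lies inside a CGI interval; shore if within 2 kb of
#' an island boundary (closed band: exactly 2,000 bp away is still
#' shore); non-CGI otherwise.
#'
#' @param features CpG coordinate table (`id`, `chrom`, `start`).
#' @param cgi_track CGI intervals as a `GRanges` (1-based inclusive).
#' @param shore_width Shore band width in bp.
#' @return Character vector: `"island"`, `"shore"` or `"non-CGI"`.
#' @export
annotate_cgi <- function(features, cgi_track, shore_width = 2000) {
  gr <- cpg_granges(features)
  out <- rep("non-CGI", length(gr))
  if (length(cgi_track) > 0) {
    inside <- IRanges::overlapsAny(gr, cgi_track)
    hits <- GenomicRanges::distanceToNearest(gr, cgi_track)
    d <- rep(NA_real_, length(gr))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    ## GRanges gap distance: a CpG k bp beyond a boundary has distance k-1
    shore <- !inside & !is.na(d) & (d + 1) <= shore_width
    out[shore] <- "shore"
    out[inside] <- "island"
  }
  out
}

#' Flag CpG overlap with interval tracks
#'
#' A CpG is flagged for a mark if it overlaps any interval of any
#' dataset carrying that mark. Datasets of the same mark are grouped by
#' the track-name prefix before the first `"."` (e.g.
#' `H3K4me3.GM12878`, `H3K4me3.K562` both feed the `H3K4me3` flag).
#'
#' @param features CpG coordinate table.
#' @param tracks Named list of `GRanges` tracks.
#' @return Logical matrix, CpGs x marks.
#' @export
annotate_tracks <- function(features, tracks) {
  if (length(tracks) == 0L) stopf("at least one track is required")
  gr <- cpg_granges(features)
  marks <- unique(sub("\\..*$", "", names(tracks)))
  out <- matrix(FALSE, length(gr), length(marks),
                dimnames = list(features$id, marks))
  for (nm in names(tracks)) {
    mk <- sub("\\..*$", "", nm)
    out[, mk] <- out[, mk] | IRanges::overlapsAny(gr, tracks[[nm]])
  }
  out
}

#' Annotate CpGs with the X-inactivation class of the nearest TSS
#'
#' Each CpG takes the escape class (`escape` / `variable` / `subject`)
#' of its nearest TSS by absolute distance, provided that distance is at
#' most `max_distance`; farther CpGs are `"unannotated"`. Equidistant
#' TSSs are resolved toward the smaller position.
#'
#' @param features CpG coordinate table.
#' @param tss TSS table (`chrom`, `pos`, `class`), as in
#'   [annotation_set()].
#' @param max_distance Annotation radius in bp.
#' @return Character vector of classes, with attribute
#'   `nearest_tss_distance`.
#' @export
annotate_escape <- function(features, tss, max_distance = 10000) {
  if (nrow(tss) == 0L) stopf("tss table is empty")
  out <- rep("unannotated", nrow(features))
  dist_out <- rep(NA_real_, nrow(features))
  for (ch in unique(features$chrom)) {
    fi <- which(features$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0L) next
    tpos <- tss$pos[ti]
    ord <- order(tpos, ti)  # smaller position wins ties
    tpos <- tpos[ord]; tcls <- tss$class[ti][ord]
    for (i in fi) {
      d <- abs(features$start[i] - tpos)
      j <- which.min(d)    # first minimum = smaller position
      dist_out[i] <- d[j]
      if (d[j] <= max_distance) out[i] <- tcls[j]
    }
  }
  attr(out, "nearest_tss_distance") <- dist_out
  out
}

#' Fisher's exact enrichment of a CpG set against the background
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' \[target & annotated, target & not; rest & annotated, rest & not\],
#' with the full chromosome-wide CpG set as background. Fold is the
#' ratio of annotation proportions (target vs background), reported as
#' its reciprocal with `direction = "depleted"` when below 1.
#'
#' @param target_ids CpG ids of the associated set (must be a subset of
#'   the background).
#' @param background_ids All background CpG ids.
#' @param annotated Logical vector or character vector: either a flag
#'   per background CpG (named, or in background order), or the set of
#'   annotated CpG ids.
#' @param label Annotation label for the result row.
#' @return One-row data frame (`EnrichmentResult`): counts, `odds_ratio`
#'   (conditional MLE), `fold`, `p`, `direction`.
#' @export
fisher_enrichment <- function(target_ids, background_ids, annotated,
                              label = "annotation") {
  if (length(target_ids) == 0L) stopf("target set is empty")
  if (!all(target_ids %in% background_ids))
    stopf("target CpGs must be a subset of the background")
  if (is.character(annotated)) {
    ann_ids <- annotated
  } else {
    flags <- if (!is.null(names(annotated))) annotated[background_ids] else annotated
    if (length(flags) != length(background_ids))
      stopf("flag vector must match the background")
    ann_ids <- background_ids[flags %in% TRUE]
  }
  n_target <- length(target_ids)
  N <- length(background_ids)
  k_in <- sum(target_ids %in% ann_ids)
  K_in <- sum(background_ids %in% ann_ids)
  tab <- matrix(c(k_in, n_target - k_in,
                  K_in - k_in, (N - n_target) - (K_in - k_in)),
                2L, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  p_t <- k_in / n_target
  p_b <- K_in / N
  fold_ratio <- if (p_b > 0) p_t / p_b else NA_real_
  depleted <- !is.na(fold_ratio) && fold_ratio < 1
  data.frame(annotation_label = label, k_in = k_in, n_target = n_target,
             K_in = K_in, N_background = N,
             odds_ratio = unname(ft$estimate),
             fold = if (depleted) 1 / fold_ratio else fold_ratio,
             direction = if (depleted) "depleted" else "enriched",
             p = ft$p.value, stringsAsFactors = FALSE)
}

#' Run the full enrichment panel for an associated CpG set
#'
#' CGI island/shore classes, every interval-track mark, and the four
#' escape classes, each Fisher-tested against the chromosome-wide
#' background.
#'
#' @param target_ids Associated CpG ids.
#' @param features Background CpG coordinate table (all X CpGs).
#' @param annotations An [annotation_set()].
#' @param cgi_track_name Name of the CGI track within the annotation
#'   set.
#' @return Data frame with one [fisher_enrichment()] row per label.
#' @export
enrichment_panel <- function(target_ids, features, annotations,
                             cgi_track_name = "CGI") {
  bg <- features$id
  rows <- list()
  cgi <- annotate_cgi(features, annotations$tracks[[cgi_track_name]])
  for (cls in c("island", "shore")) {
    rows[[paste0("CGI_", cls)]] <-
      fisher_enrichment(target_ids, bg, bg[cgi == cls], label = paste0("CGI_", cls))
  }
  other <- setdiff(names(annotations$tracks), cgi_track_name)
  if (length(other)) {
    fl <- annotate_tracks(features, annotations$tracks[other])
    for (mk in colnames(fl)) {
      rows[[mk]] <- fisher_enrichment(target_ids, bg, bg[fl[, mk]], label = mk)
    }
  }
  esc <- annotate_escape(features, annotations$tss)
  for (cls in c("escape", "variable", "subject", "unannotated")) {
    rows[[paste0("XCI_", cls)]] <-
      fisher_enrichment(target_ids, bg, bg[esc == cls],
                        label = paste0("XCI_", cls))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
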