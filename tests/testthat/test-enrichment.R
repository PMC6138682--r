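make_cpgs <- function(pos, chrom = "X") {
  data.frame(id = sprintf("cg%03d", seq_along(pos)), chrom = chrom,
             start = pos, end = pos + 1L, stringsAsFactors = FALSE)
}

test_that("CGI classification distinguishes island, shore and non-CGI", {
  cgi <- GenomicRanges::GRanges("X", IRanges::IRanges(10000, 12000))
  cpgs <- make_cpgs(c(11000,        # inside -> island
                      12000 + 1500, # 1.5 kb past the end -> shore
                      12000 + 2000, # exactly 2 kb -> still shore (closed band)
                      12000 + 2001, # 2,001 bp -> non-CGI
                      10000 - 1,    # 1 bp before start -> shore
                      500))         # far away -> non-CGI
  cls <- annotate_cgi(cpgs, cgi)
  expect_identical(cls, c("island", "shore", "shore", "non-CGI", "shore",
                          "non-CGI"))
  ## permutation invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_identical(annotate_cgi(cpgs[perm, ], cgi), cls[perm])
})

test_that("track overlap uses the any-dataset rule and the BED convention", {
  dir <- withr::local_tempdir()
  b1 <- file.path(dir, "a.bed"); b2 <- file.path(dir, "b.bed")
  writeLines("X\t100\t200", b1)          # half-open on disk: [101, 200]
  writeLines(c("X\t200\t300"), b2)       # adjacent: [201, 300]
  ann <- read_annotations(c(H3K4me3.ds1 = b1, H3K4me3.ds2 = b2,
                            H3K27me3.ds1 = b2),
                          local({ p <- file.path(dir, "tss.tsv")
                                  writeLines("chrom\tpos\tgene\tclass\nX\t1\tg\tescape", p)
                                  p }))
  cpgs <- make_cpgs(c(150, 200, 201, 350))
  fl <- annotate_tracks(cpgs, ann$tracks)
  expect_identical(colnames(fl), c("H3K4me3", "H3K27me3"))
  ## CpG in only one dataset of the mark is still flagged
  expect_identical(unname(fl[, "H3K4me3"]), c(TRUE, TRUE, TRUE, FALSE))
  ## shared boundary base 200 belongs to exactly one interval
  expect_identical(unname(fl[1:2, "H3K27me3"]), c(FALSE, FALSE))
  expect_true(fl[3, "H3K27me3"])
})

test_that("escape classes come from the nearest TSS within 10 kb", {
  tss <- data.frame(chrom = "X", pos = c(50000, 70000),
                    gene = c("g1", "g2"), class = c("variable", "subject"),
                    stringsAsFactors = FALSE)
  cpgs <- make_cpgs(c(50000,   # at a TSS -> its class
                      60000,   # equidistant -> lower-position TSS wins
                      60001,   # nearer to g2
                      80001,   # 10,001 bp away -> unannotated
                      80000))  # exactly 10 kb -> annotated
  cls <- annotate_escape(cpgs, tss)
  expect_identical(cls[1:5] |> as.character(),
                   c("variable", "variable", "subject", "unannotated",
                     "subject"))
  d <- attr(cls, "nearest_tss_distance")
  expect_identical(d[4], 10001)
})

test_that("Fisher enrichment matches the hypergeometric oracle and fold convention", {
  bg <- sprintf("cg%03d", 1:20)
  r <- fisher_enrichment(bg[1:10], bg, bg[c(1:5, 11:15)], label = "flat")
  expect_equal(r$p, 1)
  expect_equal(r$fold, 1)
  ## worked 2x2 table [[8,2],[10,40]]
  bg2 <- sprintf("cg%03d", 1:60)
  tgt <- bg2[1:10]
  ann <- bg2[c(1:8, 11:20)]   # 8 of 10 targets, 10 of 50 rest annotated
  r2 <- fisher_enrichment(tgt, bg2, ann, label = "t")
  expect_equal(r2$p, fisher_oracle(8, 2, 10, 40), tolerance = 1e-12)
  expect_identical(r2$direction, "enriched")
  expect_equal(r2$fold, (8 / 10) / (18 / 60), tolerance = 1e-12)
  ## depletion is reported as the reciprocal fold
  r3 <- fisher_enrichment(bg2[1:10], bg2, bg2[11:58], label = "d")
  expect_identical(r3$direction, "depleted")
  expect_gt(r3$fold, 1)
  expect_error(fisher_enrichment(character(0), bg2, ann), "empty")
  expect_error(fisher_enrichment("nope", bg2, ann), "subset")
  ## random tables with margins <= 50 agree with the enumeration oracle
  set.seed(40)
  for (i in 1:60) {
    n_t <- sample(2:20, 1); n_b <- n_t + sample(5:30, 1)
    bgx <- sprintf("x%03d", seq_len(n_b))
    tgtx <- bgx[seq_len(n_t)]
    annx <- sample(bgx, sample.int(n_b, 1))
    rx <- fisher_enrichment(tgtx, bgx, annx)
    expect_equal(rx$p, fisher_oracle(rx$k_in, rx$n_target - rx$k_in,
                                     rx$K_in - rx$k_in,
                                     (rx$N_background - rx$n_target) -
                                       (rx$K_in - rx$k_in)),
                 tolerance = 1e-12)
  }
})

test_that("enrichment p-values are near-uniform under random target draws", {
  set.seed(41)
  n_b <- 2000
  bg <- sprintf("cg%04d", seq_len(n_b))
  ann <- sample(bg, 600)
  ps <- replicate(1000, fisher_enrichment(sample(bg, 100), bg, ann)$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)  # discreteness-tolerant bound
})

test_that("the enrichment panel recovers a planted annotation enrichment", {
  feat <- data.frame(id = sprintf("cg%05d", 1:3000), chrom = "X",
                     start = sort(sample.int(1.4e8, 3000)) + 1e5,
                     stringsAsFactors = FALSE)
  sa <- simulate_annotations(feat, target_cpg_ids = feat$id[1:50],
                             enrichment_factor = 10, seed = 77)
  panel <- enrichment_panel(feat$id[1:50], feat, sa$annotations)
  isl <- panel[panel$annotation_label == "CGI_island", ]
  expect_identical(isl$direction, "enriched")
  expect_lt(isl$p, 0.01)
  vr <- panel[panel$annotation_label == "XCI_variable", ]
  expect_identical(vr$direction, "enriched")
  expect_lt(vr$p, 0.01)
})
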