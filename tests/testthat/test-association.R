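.ref_one_gene <- function(strand = "+") {
  make_ref(list(
    g1.t1 = list(chr = "s1", strand = strand, gene = "g1",
                 exons = list(c(1, 400), c(700, 1000)))
  ))
}

test_that("gap distances follow the closed-interval convention", {
  ref <- .ref_one_gene("+")
  lnc <- make_ts(list(
    l1 = list(chr = "s1", strand = "+", exons = list(c(1501, 1700), c(1800, 2000)))
  ))
  nb <- find_neighbors(lnc, ref)
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$distance_bp, 500L)       # 1501 - 1000 - 1
  expect_equal(nb$relation, "upstream")    # '+' gene 5' of the lncRNA
  expect_true(nb$within_window)
})

test_that("relation is resolved on the gene's strand", {
  ref <- .ref_one_gene("-")
  lnc <- make_ts(list(
    l1 = list(chr = "s1", strand = "+", exons = list(c(1501, 1700), c(1800, 2000)))
  ))
  nb <- find_neighbors(lnc, ref)
  expect_equal(nb$relation, "downstream")  # '-' gene points away from the lncRNA
})

test_that("span overlap gives relation overlap with distance zero", {
  ref <- .ref_one_gene()
  lnc <- make_ts(list(
    l1 = list(chr = "s1", strand = "-", exons = list(c(300, 500), c(600, 650)))
  ))
  nb <- find_neighbors(lnc, ref)
  expect_equal(nb$relation, "overlap")
  expect_equal(nb$distance_bp, 0L)
  expect_true(all((nb$relation == "overlap") == (nb$distance_bp == 0L)))
})

test_that("the adjacency window is inclusive at exactly window_bp", {
  ref <- .ref_one_gene()
  # gene ends at 1000; lncRNA starting at 1000 + w + 1 sits exactly w away
  w <- 10000L
  lnc <- make_ts(list(
    at = list(chr = "s1", strand = "+",
              exons = list(c(1000 + w + 1, 1000 + w + 200),
                           c(1000 + w + 300, 1000 + w + 500))),
    beyond = list(chr = "s1", strand = "+",
                  exons = list(c(1000 + w + 2, 1000 + w + 200),
                               c(1000 + w + 300, 1000 + w + 500)))
  ))
  nb <- find_neighbors(lnc, ref, window_bp = w)
  expect_true(nb$within_window[nb$lnc_id == "at"])
  expect_equal(nb$distance_bp[nb$lnc_id == "at"], w)
  expect_false(nb$within_window[nb$lnc_id == "beyond"])
})

test_that("genes beyond the reporting horizon are omitted", {
  ref <- .ref_one_gene()
  lnc <- make_ts(list(
    far = list(chr = "s1", strand = "+",
               exons = list(c(60000, 60200), c(60400, 60600)))
  ))
  expect_equal(nrow(find_neighbors(lnc, ref, max_report_bp = 50000L)), 0L)
  expect_equal(nrow(find_neighbors(lnc, ref, max_report_bp = 60000L)), 1L)
})

test_that("neighbour links match a brute-force scan on a dense layout", {
  g <- generate_genome(n_scaffolds = 1L, scaffold_len = 2000000L,
                       n_genes = 40L, seed = 5L, intergenic_bp = 4000L,
                       intron_range = c(500L, 1500L))
  set.seed(77)
  lnc <- random_candidates(g$annotation, scaffold_len = 2000000L, n = 80,
                           strands = c("+", "-"))
  got <- find_neighbors(lnc, g$annotation, window_bp = 10000L,
                        max_report_bp = 50000L)
  exp <- oracle_neighbors(lnc, g$annotation)
  key <- function(d) paste(d$lnc_id, d$gene_id, d$distance_bp)
  expect_setequal(key(got), key(exp))
  # symmetry of the gap: swap roles and re-measure
  swap <- got[got$relation != "overlap", ]
  for (k in seq_len(min(20, nrow(swap)))) {
    gspan <- g$annotation$genes[swap$gene_id[k]]
    lspan <- tx_spans(lnc)[swap$lnc_id[k]]
    d1 <- max(GenomicRanges::start(gspan) - GenomicRanges::end(lspan) - 1,
              GenomicRanges::start(lspan) - GenomicRanges::end(gspan) - 1)
    expect_equal(swap$distance_bp[k], d1)
  }
})

test_that("shrinking the window never adds within-window links", {
  fx <- get_default_fixture()
  report <- run_cascade(fx$candidates, fx$sequences, fx$hits)
  lnc <- tx_subset(fx$candidates, report$kept)
  wide <- find_neighbors(lnc, fx$annotation, window_bp = 10000L)
  narrow <- find_neighbors(lnc, fx$annotation, window_bp = 2000L)
  key <- function(d) paste(d$lnc_id, d$gene_id)
  expect_true(all(key(narrow)[narrow$within_window] %in%
                  key(wide)[wide$within_window]))
  # each lncRNA: at most one nearest link per side plus overlaps, no dupes
  expect_equal(anyDuplicated(key(wide)), 0L)
  per_side <- table(wide$lnc_id[wide$relation != "overlap"])
  expect_true(all(per_side <= 2))
})

test_that("overlap geometry reports intersection length and gene part", {
  ref <- .ref_one_gene()
  lnc <- make_ts(list(
    # lncRNA span [100,400] vs gene span [1,1000]: closed intersection = 301
    ex_ovl = list(chr = "s1", strand = "-", exons = list(c(100, 250), c(300, 400))),
    in_ovl = list(chr = "s1", strand = "+", exons = list(c(450, 500), c(550, 620))),
    away = list(chr = "s1", strand = "+", exons = list(c(5000, 5200)))
  ))
  rep_ <- overlap_report(lnc, ref)
  expect_setequal(rep_$lnc_id, c("ex_ovl", "in_ovl"))
  ex_row <- rep_[rep_$lnc_id == "ex_ovl", ]
  expect_equal(ex_row$overlap_bp, 301L)
  expect_equal(ex_row$part, "exon")
  expect_equal(ex_row$orientation, "antisense")
  in_row <- rep_[rep_$lnc_id == "in_ovl", ]
  expect_equal(in_row$part, "intron")   # sits wholly in the 401..699 intron
  expect_equal(in_row$orientation, "sense")

  # lncRNA span [100,400] against a gene span [300,900]: intersection 101
  ref2 <- make_ref(list(g.t1 = list(chr = "s1", strand = "+", gene = "g",
                                    exons = list(c(300, 900)))))
  one <- make_ts(list(l = list(chr = "s1", strand = "+",
                               exons = list(c(100, 200), c(350, 400)))))
  expect_equal(overlap_report(one, ref2)$overlap_bp, 101L)
})

test_that("random pair overlap lengths equal the naive computation", {
  fx <- get_default_fixture()
  set.seed(8)
  lnc <- random_candidates(fx$annotation, scaffold_len = 400000L, n = 60)
  rep_ <- overlap_report(lnc, fx$annotation)
  spans <- tx_spans(lnc)
  genes <- fx$annotation$genes
  for (k in seq_len(nrow(rep_))) {
    ls <- spans[rep_$lnc_id[k]]; gs <- genes[rep_$gene_id[k]]
    expect_equal(rep_$overlap_bp[k],
                 min(GenomicRanges::end(ls), GenomicRanges::end(gs)) -
                 max(GenomicRanges::start(ls), GenomicRanges::start(gs)) + 1)
  }
})

test_that("link annotation attaches co-expression and labels strength", {
  ex <- generate_expression(c("lncA", "geneA", "lncB"), n_samples = 12,
                            design = expression_design(
                              coexpr = data.frame(id_x = "lncA", id_y = "geneA",
                                                  target_r = 0.95)),
                            seed = 99)
  links <- data.frame(lnc_id = c("lncA", "lncB"), gene_id = c("geneA", "ghost"),
                      seqnames = "s1", relation = c("overlap", "upstream"),
                      distance_bp = c(0L, 400L), within_window = TRUE,
                      gene_strand = "+")
  expect_warning(out <- annotate_links(links, ex$matrix), "unannotated")
  expect_true(out$strong[out$lnc_id == "lncA"])
  expect_true(is.na(out$r[out$lnc_id == "lncB"]))
})

test_that("independent pairs are rarely labelled strong", {
  hits <- vapply(1:40, function(k) {
    ex <- generate_expression(c("x", "y"), n_samples = 12,
                              design = expression_design(), seed = 3000 + k)
    isTRUE(pearson_coexpression(ex$matrix, data.frame("x", "y"))$strong)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
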