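# a small hand-built reference: two genes on s1 (one per strand), one on s2
.ref2 <- function() {
  make_ref(list(
    g1.t1 = list(chr = "s1", strand = "+", gene = "g1",
                 exons = list(c(1000, 1200), c(2000, 2300), c(3000, 3400))),
    g2.t1 = list(chr = "s1", strand = "-", gene = "g2",
                 exons = list(c(20000, 20400), c(22000, 22500))),
    g3.t1 = list(chr = "s2", strand = "+", gene = "g3",
                 exons = list(c(5000, 5300), c(6000, 6500)))
  ))
}

test_that("hand-built cases hit every category", {
  ref <- .ref2()
  ts <- make_ts(list(
    between = list(chr = "s1", strand = "+", exons = list(c(8000, 8200),
                                                          c(8500, 8700))),
    intron_as = list(chr = "s1", strand = "+",
                     exons = list(c(20500, 20600), c(20800, 20900))),
    intron_s = list(chr = "s1", strand = "+",
                    exons = list(c(1300, 1400), c(1600, 1700))),
    exon_s = list(chr = "s1", strand = "+", exons = list(c(1100, 1300),
                                                         c(1500, 1600))),
    exon_as = list(chr = "s1", strand = "-", exons = list(c(2100, 2400),
                                                          c(2600, 2700))),
    junction = list(chr = "s1", strand = "+",
                    exons = list(c(1100, 1200), c(2000, 2100))),
    dangling = list(chr = "s1", strand = "-",
                    exons = list(c(21000, 21100), c(23000, 23100)))
  ))
  cl <- classify_transcripts(ts, ref)
  got <- setNames(as.character(cl$category), cl$transcript_id)
  expect_equal(got[["between"]], "INTERGENIC")
  expect_equal(got[["intron_as"]], "INTRONIC_ANTISENSE")
  expect_equal(got[["intron_s"]], "INTRONIC_SENSE")
  expect_equal(got[["exon_s"]], "EXONIC_SENSE")
  expect_equal(got[["exon_as"]], "EXONIC_ANTISENSE")
  # shares the intron (1201,1999): junction wins over its exon overlaps
  expect_equal(got[["junction"]], "JUNCTION_SHARE")
  # overlaps g2's span but touches only intronic sequence and extends past
  # the gene end
  expect_equal(got[["dangling"]], "UNCLASSIFIED")
})

test_that("unstranded candidates can only be intergenic or unclassified", {
  ref <- .ref2()
  ts <- make_ts(list(
    star_in_gene = list(chr = "s1", strand = "*",
                        exons = list(c(1100, 1300), c(1500, 1600))),
    star_between = list(chr = "s1", strand = "*",
                        exons = list(c(9000, 9100), c(9300, 9400)))
  ))
  cl <- classify_transcripts(ts, ref)
  got <- setNames(as.character(cl$category), cl$transcript_id)
  expect_equal(got[["star_in_gene"]], "UNCLASSIFIED")
  expect_equal(got[["star_between"]], "INTERGENIC")
})

test_that("missing scaffolds follow the configured policy", {
  ref <- .ref2()
  ts <- make_ts(list(
    lost = list(chr = "s99", strand = "+", exons = list(c(1, 100), c(200, 300)))
  ))
  cl <- classify_transcripts(ts, ref, on_missing_scaffold = "lenient")
  expect_equal(as.character(cl$category), "INTERGENIC")
  expect_error(classify_transcripts(ts, ref, on_missing_scaffold = "error"),
               "s99")
})

test_that("planted fixture classes are recovered in full", {
  fx <- get_default_fixture()
  report <- run_cascade(fx$candidates, fx$sequences, fx$hits)
  lnc <- tx_subset(fx$candidates, report$kept)
  cl <- classify_transcripts(lnc, fx$annotation)
  m <- merge(cl, fx$truth$candidates[, c("transcript_id", "planted_class")])
  expect_equal(nrow(m), length(lnc))
  expect_true(all(as.character(m$category) == m$planted_class))
})

test_that("classification agrees with a naive all-pairs oracle on random candidates", {
  fx <- get_default_fixture()
  set.seed(101)
  rnd <- random_candidates(fx$annotation, scaffold_len = 400000L, n = 150)
  got <- classify_transcripts(rnd, fx$annotation)
  exp <- oracle_classify(rnd, fx$annotation)
  expect_equal(as.character(got$category), exp)
})

test_that("classification is invariant under exon-list permutation and translation", {
  ref <- .ref2()
  ts <- make_ts(list(
    a = list(chr = "s1", strand = "+", exons = list(c(1100, 1300), c(1500, 1600)))
  ))
  base <- as.character(classify_transcripts(ts, ref)$category)

  # permuted exon input order
  gr <- tx_exons(ts)[c(2, 1)]
  perm <- transcript_set(gr)
  expect_equal(as.character(classify_transcripts(perm, ref)$category), base)

  # translate candidate and reference together by a constant offset
  shift_ts <- function(x, by) {
    g <- tx_exons(x)
    g2 <- GenomicRanges::shift(g, by)
    transcript_set(g2)
  }
  ts2 <- shift_ts(ts, 5000L)
  ref2 <- annotation_index(shift_ts(ref$tx, 5000L))
  expect_equal(as.character(classify_transcripts(ts2, ref2)$category), base)
})

test_that("candidates identical to a reference isoform are flagged known", {
  ref <- .ref2()
  ts <- make_ts(list(
    copy = list(chr = "s1", strand = "+",
                exons = list(c(950, 1200), c(2000, 2300), c(3000, 3500))),
    novel = list(chr = "s1", strand = "+",
                 exons = list(c(1100, 1200), c(2000, 2100)))
  ))
  known <- flag_known_transcripts(ts, ref)
  expect_true(known[["copy"]])    # same intron chain, ragged ends
  expect_false(known[["novel"]])  # shares one junction only
})

test_that("locus clustering is transitive and order-invariant", {
  ts <- make_ts(list(
    a = list(chr = "s1", strand = "+", exons = list(c(100, 200), c(400, 500))),
    b = list(chr = "s1", strand = "-", exons = list(c(450, 600))),
    c = list(chr = "s1", strand = "+", exons = list(c(580, 700), c(900, 950))),
    d = list(chr = "s1", strand = "+", exons = list(c(5000, 5100))),
    e = list(chr = "s2", strand = "+", exons = list(c(100, 200)))
  ))
  cl <- cluster_loci(ts)
  mem <- setNames(cl$members$locus_id, cl$members$transcript_id)
  # a-b overlap, b-c overlap, a-c disjoint: one cluster by transitivity
  expect_equal(length(unique(mem[c("a", "b", "c")])), 1L)
  expect_false(mem[["d"]] == mem[["a"]])
  expect_false(mem[["e"]] == mem[["d"]])
  expect_equal(nrow(cl$loci), 3L)

  # reversed input order gives the same partition and ids
  gr <- tx_exons(ts)
  cl2 <- cluster_loci(transcript_set(rev(gr)))
  expect_equal(cl2$members[order(cl2$members$transcript_id), ],
               cl$members[order(cl$members$transcript_id), ],
               ignore_attr = TRUE)
})

test_that("cluster partition matches an igraph transitive-closure oracle", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:5) {
    n <- 60
    spec <- lapply(seq_len(n), function(i) {
      st <- sample.int(20000, 1)
      list(chr = sample(c("s1", "s2"), 1), strand = sample(c("+", "-"), 1),
           exons = list(c(st, st + sample(50:400, 1))))
    })
    names(spec) <- sprintf("t%02d", seq_len(n))
    ts <- make_ts(spec)
    cl <- cluster_loci(ts)

    ex <- tx_exons(ts)
    tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
    hits <- GenomicRanges::findOverlaps(ex, ignore.strand = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = tid[S4Vectors::queryHits(hits)],
                 to = tid[S4Vectors::subjectHits(hits)]),
      directed = FALSE, vertices = tx_ids(ts))
    comp <- igraph::components(g)$membership
    # same partition: cluster labels must be a bijection of components
    mem <- setNames(cl$members$locus_id, cl$members$transcript_id)
    expect_equal(length(unique(mem)), igraph::components(g)$no)
    tab <- table(mem[names(comp)], comp)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("the category-by-sample table adds up", {
  fx <- get_default_fixture()
  report <- run_cascade(fx$candidates, fx$sequences, fx$hits)
  lnc <- tx_subset(fx$candidates, report$kept)
  cl <- classify_transcripts(lnc, fx$annotation)
  tab <- classification_table(cl, expr = fx$expression)
  expect_equal(unname(tab["Total", ]), unname(colSums(tab[rownames(tab) != "Total", ])))
  expect_equal(tab["Total", "all"], length(lnc))
  # categories partition the candidate set
  expect_equal(sum(tab[rownames(tab) != "Total", "all"]), length(lnc))

  empty <- classification_table(classify_transcripts(
    tx_subset(lnc, character(0)), fx$annotation))
  expect_true(all(empty == 0))
})
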