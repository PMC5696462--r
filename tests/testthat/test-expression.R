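.profile_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- LETTERS[seq_len(ncol(m))]
  m
}

test_that("specificity rules evaluate as stated", {
  m <- .profile_mat(
    t1 = c(10, 0.5, 0.2, 0.1),   # passes both rules
    t2 = c(2.5, 0.1, 0.1, 0.1),  # fails high cut
    t3 = c(50, 4, 3, 2)          # fails high/low, passes 10-fold (50/4 = 12.5)
  )
  and_calls <- call_specific(m, combine = "AND")
  or_calls <- call_specific(m, combine = "OR")
  get <- function(df, id, col) df[df$transcript_id == id, col]

  expect_true(get(and_calls, "t1", "rule_high_low"))
  expect_true(get(and_calls, "t1", "rule_fold"))
  expect_true(get(and_calls, "t1", "specific"))
  expect_equal(get(and_calls, "t1", "focal_sample"), "A")

  expect_false(get(and_calls, "t2", "specific"))
  expect_false(get(and_calls, "t2", "rule_high_low"))

  expect_false(get(and_calls, "t3", "rule_high_low"))
  expect_true(get(and_calls, "t3", "rule_fold"))
  expect_false(get(and_calls, "t3", "specific"))
  expect_true(get(or_calls, "t3", "specific"))
})

test_that("ties for the expression maximum disqualify a transcript", {
  m <- .profile_mat(tie = c(10, 10, 0.1, 0.1))
  res <- call_specific(m)
  expect_true(is.na(res$focal_sample))
  expect_false(res$specific)
  expect_error(call_specific(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("permuting sample columns permutes focal labels consistently", {
  fx <- get_default_fixture()
  lnc_ids <- fx$truth$expression$transcript_id[
    fx$truth$expression$role == "specific"]
  m <- fx$expression[lnc_ids, ]
  perm <- c(3, 1, 4, 2)
  res1 <- call_specific(m)
  res2 <- call_specific(m[, perm])
  expect_equal(res1$specific, res2$specific)
  expect_equal(res1$focal_sample, res2$focal_sample)
})

test_that("raising the fold cut never adds specificity calls", {
  fx <- get_default_fixture()
  m <- fx$expression
  prev <- rep(TRUE, nrow(m))
  for (fc in c(2, 5, 10, 50)) {
    cur <- call_specific(m, fold_cut = fc)$specific
    expect_true(all(!cur | prev))  # cur implies prev
    prev <- cur
  }
})

test_that("identical groups give p-values of 1 and no differential calls", {
  set.seed(9)
  vals <- matrix(rlnorm(30), nrow = 5)
  m <- cbind(vals[, 1:3], vals[, 1:3])
  dimnames(m) <- list(paste0("t", 1:5), paste0("S", 1:6))
  res <- call_differential(m, paste0("S", 1:3), paste0("S", 4:6))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
})

test_that("overlapping groups are rejected", {
  m <- .profile_mat(t1 = c(1, 2, 3, 4))
  expect_error(call_differential(m, c("A", "B"), c("B", "C")), "overlap")
})

test_that("a planted shift is recovered with BH-controlled false positives", {
  set.seed(42)
  n_null <- 100
  ga <- paste0("A", 1:3); gb <- paste0("B", 1:3)
  m <- matrix(rlnorm(n_null * 6, log(10), 0.1), nrow = n_null,
              dimnames = list(paste0("null", 1:n_null), c(ga, gb)))
  planted <- c(rlnorm(3, log(10), 0.05), rlnorm(3, log(50), 0.05))
  m <- rbind(m, planted = planted)
  res <- call_differential(m, ga, gb)
  expect_true(res$significant[res$transcript_id == "planted"])
  expect_gt(res$log2fc[res$transcript_id == "planted"], 2)
  # false positives no worse than the BH expectation at this m
  expect_lte(sum(res$significant) - 1, ceiling(0.05 * nrow(m)))
})

test_that("BH q-values match the step-up formula on a hand-computed vector", {
  # p = (0.01, 0.02, 0.03, 0.04), m = 4: q_i = min_{j>=i} p_j * m / j = 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  # the same numbers flow through call_differential: build data whose
  # t-tests are irrelevant, then check our q == p.adjust(p)
  set.seed(13)
  m <- matrix(rlnorm(40 * 6), nrow = 40,
              dimnames = list(paste0("t", 1:40), paste0("S", 1:6)))
  res <- call_differential(m, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
  expect_true(all(res$q_value >= res$p_value))
})

test_that("fewer than two replicates falls back to flagged fold-change calls", {
  m <- .profile_mat(up = c(1, 1, 20, 20), flat = c(5, 5, 5, 5))
  res <- call_differential(m, "A", c("C", "D"))
  expect_true(all(res$method == "fold_change_only"))
  expect_true(all(is.na(res$p_value)))
  expect_true(res$significant[res$transcript_id == "up"])
  expect_false(res$significant[res$transcript_id == "flat"])
})

test_that("Pearson identities hold exactly on raw profiles", {
  m <- .profile_mat(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1), z = c(2, 4, 6, 8),
                    k = c(5, 5, 5, 5))
  res <- pearson_coexpression(m, data.frame(a = c("x", "x", "x"),
                                            b = c("x", "y", "z")))
  expect_equal(res$r, c(1, -1, 1))
  expect_true(all(res$strong))
  expect_equal(res$p_value[1], 0)

  deg <- pearson_coexpression(m, data.frame(a = "x", b = "k"))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$r) && is.na(deg$strong))
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(21)
  m <- matrix(rlnorm(24), nrow = 2, dimnames = list(c("a", "b"), paste0("S", 1:12)))
  r0 <- pearson_coexpression(m, data.frame("a", "b"))$r
  m2 <- m; m2["a", ] <- 3.7 * m2["a", ] + 11
  expect_equal(pearson_coexpression(m2, data.frame("a", "b"))$r, r0)
})

test_that("pairs planted at r = 0.9 are estimated near target and mostly strong", {
  reps <- 60
  rs <- vapply(seq_len(reps), function(k) {
    ex <- generate_expression(c("x", "y"), n_samples = 12,
                              design = expression_design(
                                coexpr = data.frame(id_x = "x", id_y = "y",
                                                    target_r = 0.9)),
                              seed = 7000 + k)
    pearson_coexpression(ex$matrix, data.frame("x", "y"))$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.1)
  expect_gte(mean(abs(rs) > 0.8), 0.9)
})

test_that("null-matrix q-values stay under the FDR target", {
  set.seed(55)
  fracs <- vapply(1:30, function(k) {
    m <- matrix(rlnorm(50 * 6, log(5), 0.5), nrow = 50,
                dimnames = list(paste0("t", 1:50), paste0("S", 1:6)))
    res <- call_differential(m, paste0("S", 1:3), paste0("S", 4:6))
    mean(res$q_value < 0.05)
  }, numeric(1))
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lte(mean(fracs), 0.05 + 3 * se)
})

test_that("average-linkage clustering exports a Newick tree", {
  skip_if_not_installed("ape")
  set.seed(2)
  m <- matrix(rlnorm(40), nrow = 10,
              dimnames = list(paste0("t", 1:10), paste0("S", 1:4)))
  hc <- cluster_expression(m)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$method, "average")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_cluster_tree(hc, path)
  tree <- ape::read.tree(path)
  expect_equal(sort(tree$tip.label), sort(paste0("t", 1:10)))
})
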