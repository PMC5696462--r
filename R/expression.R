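#' Sample-specific expression calls
#'
#' A transcript is a candidate for specificity in its highest-expressed
#' (focal) sample only; ties for the maximum disqualify it. Two rules
#' are evaluated against all non-focal samples:
#'
#' * `rule_high_low`: focal FPKM > `high_cut` AND every other sample
#'   < `low_cut` (defaults 3 and 1 FPKM);
#' * `rule_fold`: focal FPKM >= `fold_cut` x the largest other value
#'   (default 10-fold; the divisor is floored at `eps` FPKM to avoid
#'   division by zero).
#'
#' `combine = "AND"` (default) requires both rules, the stricter reading;
#' `"OR"` accepts either.
#'
#' @param mat FPKM matrix, rows = transcripts, columns = samples (>= 2)
#' @param high_cut,low_cut,fold_cut rule thresholds
#' @param combine `"AND"` or `"OR"`
#' @param eps floor for the fold-rule divisor, in FPKM
#' @return data.frame `transcript_id`, `focal_sample` (NA on a tie),
#'   `focal_fpkm`, `max_other`, `rule_high_low`, `rule_fold`, `specific`
#' @export
call_specific <- function(mat, high_cut = 3, low_cut = 1, fold_cut = 10,
                          combine = c("AND", "OR"), eps = 0.01) {
  combine <- match.arg(combine)
  if (ncol(mat) < 2L) stop("specificity calling needs >= 2 samples")
  top <- apply(mat, 1L, max)
  n_top <- rowSums(mat == top)
  focal_idx <- max.col(mat, ties.method = "first")
  focal <- colnames(mat)[focal_idx]
  focal[n_top > 1L] <- NA_character_

  others_max <- vapply(seq_len(nrow(mat)), function(i) {
    max(mat[i, -focal_idx[i]])
  }, numeric(1))
  others_below_low <- vapply(seq_len(nrow(mat)), function(i) {
    all(mat[i, -focal_idx[i]] < low_cut)
  }, logical(1))

  rule_hl <- top > high_cut & others_below_low
  rule_fold <- top >= fold_cut * pmax(others_max, eps)
  spec <- if (combine == "AND") rule_hl & rule_fold else rule_hl | rule_fold
  spec[is.na(focal)] <- FALSE
  rule_hl[is.na(focal)] <- FALSE
  rule_fold[is.na(focal)] <- FALSE

  data.frame(transcript_id = rownames(mat), focal_sample = focal,
             focal_fpkm = top, max_other = others_max,
             rule_high_low = rule_hl, rule_fold = rule_fold,
             specific = spec, row.names = NULL)
}

#' Differential expression between two sample groups
#'
#' Welch's two-sided t-test on log2(FPKM + pseudocount), with
#' Benjamini-Hochberg q-values computed over all tested transcripts. A
#' transcript is called significant when p < `p_cut` AND q < `q_cut`.
#' With fewer than two replicates in either group no test is possible;
#' calls then fall back to fold change alone (|log2fc| >= `lfc_fallback`)
#' and are flagged via the `method` column.
#'
#' @param mat FPKM matrix
#' @param group_a,group_b disjoint character vectors of sample names
#' @param p_cut,q_cut significance thresholds (strict <)
#' @param pseudocount added to FPKM before log2
#' @param lfc_fallback |log2fc| threshold used only in the
#'   fold-change-only fallback
#' @return data.frame `transcript_id`, `mean_a`, `mean_b` (mean log2
#'   expression per group), `log2fc` (B relative to A), `p_value`,
#'   `q_value`, `significant`, `method`
#' @export
call_differential <- function(mat, group_a, group_b, p_cut = 0.05,
                              q_cut = 0.05, pseudocount = 0.1,
                              lfc_fallback = 1) {
  if (length(intersect(group_a, group_b))) {
    stop("sample groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  miss <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(miss)) stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))

  la <- log2(mat[, group_a, drop = FALSE] + pseudocount)
  lb <- log2(mat[, group_b, drop = FALSE] + pseudocount)
  mean_a <- rowMeans(la); mean_b <- rowMeans(lb)
  lfc <- mean_b - mean_a

  can_test <- length(group_a) >= 2L && length(group_b) >= 2L
  if (can_test) {
    p <- vapply(seq_len(nrow(mat)), function(i) {
      a <- la[i, ]; b <- lb[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      }
      stats::t.test(a, b)$p.value
    }, numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    sig <- p < p_cut & q < q_cut
    method <- "welch_t_log2"
  } else {
    p <- rep(NA_real_, nrow(mat)); q <- rep(NA_real_, nrow(mat))
    sig <- abs(lfc) >= lfc_fallback
    method <- "fold_change_only"
  }
  data.frame(transcript_id = rownames(mat), mean_a = mean_a, mean_b = mean_b,
             log2fc = lfc, p_value = p, q_value = q, significant = sig,
             method = method, row.names = NULL)
}

#' Pearson co-expression for lncRNA-mRNA pairs
#'
#' Computes Pearson's r over the shared samples of each pair, with a
#' two-sided p-value from t = r * sqrt((n - 2) / (1 - r^2)), and labels
#' a pair strong when |r| > `strong_cut`. Correlation is computed on raw
#' FPKM; set `log_scale = TRUE` for log2(FPKM + pseudocount). Pairs
#' with a constant profile have undefined r and are flagged `degenerate`
#' (r, p and the strength label are NA).
#'
#' @param mat FPKM matrix with >= 3 samples
#' @param pairs data.frame (or 2-column matrix) of id pairs; columns are
#'   taken as (lncRNA id, mRNA id)
#' @param strong_cut |r| threshold for the strong label (strict >)
#' @param log_scale compute r on log2(FPKM + pseudocount)
#' @param pseudocount used only when `log_scale = TRUE`
#' @return data.frame `lnc_id`, `mrna_id`, `n`, `r`, `p_value`,
#'   `strong`, `degenerate`
#' @export
pearson_coexpression <- function(mat, pairs, strong_cut = 0.8,
                                 log_scale = FALSE, pseudocount = 0.1) {
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2L)
  if (ncol(mat) < 3L) stop("co-expression needs >= 3 shared samples")
  x <- if (log_scale) log2(mat + pseudocount) else mat
  n <- ncol(x)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- as.character(pairs[[1L]][k]); b <- as.character(pairs[[2L]][k])
    if (!a %in% rownames(x) || !b %in% rownames(x)) {
      return(data.frame(lnc_id = a, mrna_id = b, n = n, r = NA_real_,
                        p_value = NA_real_, strong = NA, degenerate = NA,
                        missing = TRUE))
    }
    va <- x[a, ]; vb <- x[b, ]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      return(data.frame(lnc_id = a, mrna_id = b, n = n, r = NA_real_,
                        p_value = NA_real_, strong = NA, degenerate = TRUE,
                        missing = FALSE))
    }
    r <- stats::cor(va, vb)
    p <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    data.frame(lnc_id = a, mrna_id = b, n = n, r = r, p_value = p,
               strong = abs(r) > strong_cut, degenerate = FALSE,
               missing = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average-linkage expression clustering
#'
#' Hierarchical clustering of transcripts on the 1 - Pearson correlation
#' distance with average linkage — the layout used for expression
#' heatmaps. Rendering is left to external viewers; the tree can be
#' exported in Newick via [write_cluster_tree()].
#'
#' @param mat FPKM matrix (rows clustered); constant rows are dropped
#' @return an [stats::hclust] object
#' @export
cluster_expression <- function(mat) {
  keep <- apply(mat, 1L, stats::sd) > 0
  m <- mat[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("need >= 2 non-constant transcripts to cluster")
  d <- stats::as.dist(1 - stats::cor(t(m)))
  stats::hclust(d, method = "average")
}

#' @rdname cluster_expression
#' @param hc an `hclust` from [cluster_expression()]
#' @param path output Newick file
#' @export
write_cluster_tree <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export needs the 'ape' package")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
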