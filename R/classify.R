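#' Positional classification of lncRNA candidates
#'
#' Each candidate is assigned exactly one of seven categories relative
#' to the reference annotation, decided by fixed precedence:
#'
#' 1. `JUNCTION_SHARE` — at least one intron identical (coordinates and
#'    strand) to a reference intron;
#' 2. `EXONIC_SENSE` — >=1 bp exon-exon overlap with a reference exon on
#'    the same strand;
#' 3. `EXONIC_ANTISENSE` — exon-exon overlap on the opposite strand;
#' 4. `INTRONIC_SENSE` — the whole candidate lies within a single intron
#'    of one reference transcript, same strand;
#' 5. `INTRONIC_ANTISENSE` — as 4 on the opposite strand;
#' 6. `INTERGENIC` — no overlap with any reference gene span;
#' 7. `UNCLASSIFIED` — anything else (partial gene-span overlap without
#'    exon overlap, or unknown strand where strand matters).
#'
#' Candidates with strand `*` can only be `INTERGENIC` or
#' `UNCLASSIFIED`. The evidence column lists the reference genes behind
#' the decisive relation.
#'
#' @param ts candidate `TranscriptSet`
#' @param ref an `AnnotationIndex`
#' @param intronic_partial if TRUE, category 5 also admits partial
#'   intron overlap on the opposite strand (instead of full
#'   containment); default FALSE, mirroring the sense definition
#' @param on_missing_scaffold `"lenient"` treats candidates on scaffolds
#'   absent from the reference as having no overlaps (they classify as
#'   INTERGENIC); `"error"` aborts
#' @return data.frame `transcript_id`, `category` (factor with the seven
#'   levels), `evidence` (comma-separated reference gene ids, `""` for
#'   intergenic)
#' @export
classify_transcripts <- function(ts, ref, intronic_partial = FALSE,
                                 on_missing_scaffold = c("lenient", "error")) {
  on_missing_scaffold <- match.arg(on_missing_scaffold)
  stopifnot(inherits(ts, "TranscriptSet"), inherits(ref, "AnnotationIndex"))
  categories <- c("JUNCTION_SHARE", "EXONIC_SENSE", "EXONIC_ANTISENSE",
                  "INTRONIC_SENSE", "INTRONIC_ANTISENSE", "INTERGENIC",
                  "UNCLASSIFIED")
  tab <- tx_table(ts)
  n <- nrow(tab)
  if (n == 0L) {
    return(data.frame(transcript_id = character(),
                      category = factor(character(), levels = categories),
                      evidence = character()))
  }
  if (on_missing_scaffold == "error") {
    miss <- setdiff(unique(tab$seqnames),
                    as.character(GenomicRanges::seqnames(ref$genes)))
    if (length(miss)) stop("candidate scaffold(s) absent from reference: ",
                           paste(miss, collapse = ", "))
  }

  cand_ex <- tx_exons(ts)
  cand_tid <- as.character(S4Vectors::mcols(cand_ex)$transcript_id)
  cand_intr <- tx_introns(ts)
  spans <- tx_spans(ts)
  idx <- stats::setNames(seq_len(n), tab$transcript_id)

  cat_out <- rep(NA_character_, n)
  ev <- vector("list", n)
  stranded <- tab$strand %in% c("+", "-")

  ref_str <- as.character(GenomicRanges::strand(ref$exons))
  ref_gid <- as.character(S4Vectors::mcols(ref$exons)$gene_id)

  assign_cat <- function(i, category, genes) {
    fresh <- is.na(cat_out[i])
    cat_out[i[fresh]] <<- category
    for (j in which(fresh)) {
      ev[[i[j]]] <<- unique(genes[[j]])
    }
  }

  # 1. shared splice junction: candidate intron == reference intron,
  #    same strand
  if (length(cand_intr) && length(ref$introns)) {
    key <- function(gr) paste0(GenomicRanges::seqnames(gr), ":",
                               GenomicRanges::start(gr), "-",
                               GenomicRanges::end(gr), ":",
                               GenomicRanges::strand(gr))
    ci_tid <- as.character(S4Vectors::mcols(cand_intr)$transcript_id)
    ci_str <- as.character(GenomicRanges::strand(cand_intr)) %in% c("+", "-")
    m <- match(key(cand_intr), key(ref$introns))
    hit <- !is.na(m) & ci_str
    if (any(hit)) {
      gid_hit <- as.character(S4Vectors::mcols(ref$introns)$gene_id)[m[hit]]
      by <- split(gid_hit, ci_tid[hit])
      i <- idx[names(by)]
      assign_cat(i, "JUNCTION_SHARE", unname(by))
    }
  }

  # 2./3. exon-exon overlap, sense then antisense
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(cand_ex, ref$exons, ignore.strand = TRUE))
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    cstr <- as.character(GenomicRanges::strand(cand_ex))[q]
    known_str <- cstr %in% c("+", "-")
    same <- known_str & cstr == ref_str[s]
    oppo <- known_str & cstr != ref_str[s] & ref_str[s] %in% c("+", "-")
    for (sense in c(TRUE, FALSE)) {
      sel <- if (sense) same else oppo
      if (!any(sel)) next
      by <- split(ref_gid[s[sel]], cand_tid[q[sel]])
      assign_cat(idx[names(by)], if (sense) "EXONIC_SENSE" else "EXONIC_ANTISENSE",
                 unname(by))
    }
  }

  # 4./5. intronic containment (whole candidate span within ONE intron
  #       of one reference transcript)
  if (length(ref$introns)) {
    within <- suppressWarnings(
      GenomicRanges::findOverlaps(spans, ref$introns, type = "within",
                                  ignore.strand = TRUE))
    ri_str <- as.character(GenomicRanges::strand(ref$introns))
    ri_gid <- as.character(S4Vectors::mcols(ref$introns)$gene_id)
    if (length(within)) {
      q <- S4Vectors::queryHits(within); s <- S4Vectors::subjectHits(within)
      cstr <- tab$strand[q]
      ok <- cstr %in% c("+", "-")
      same <- ok & cstr == ri_str[s]
      oppo <- ok & cstr != ri_str[s]
      for (sense in c(TRUE, FALSE)) {
        sel <- if (sense) same else oppo
        if (!any(sel)) next
        by <- split(ri_gid[s[sel]], tab$transcript_id[q[sel]])
        assign_cat(idx[names(by)],
                   if (sense) "INTRONIC_SENSE" else "INTRONIC_ANTISENSE",
                   unname(by))
      }
    }
    if (intronic_partial) {
      part <- suppressWarnings(
        GenomicRanges::findOverlaps(cand_ex, ref$introns, ignore.strand = TRUE))
      if (length(part)) {
        q <- S4Vectors::queryHits(part); s <- S4Vectors::subjectHits(part)
        cstr <- as.character(GenomicRanges::strand(cand_ex))[q]
        sel <- cstr %in% c("+", "-") & cstr != ri_str[s]
        if (any(sel)) {
          by <- split(ri_gid[s[sel]], cand_tid[q[sel]])
          assign_cat(idx[names(by)], "INTRONIC_ANTISENSE", unname(by))
        }
      }
    }
  }

  # 6. intergenic: no gene-span overlap at all
  gene_ov <- suppressWarnings(
    GenomicRanges::countOverlaps(spans, ref$genes, ignore.strand = TRUE))
  free <- which(is.na(cat_out) & gene_ov == 0L)
  cat_out[free] <- "INTERGENIC"

  # 7. the rest
  cat_out[is.na(cat_out)] <- "UNCLASSIFIED"
  # unstranded candidates can only be intergenic or unclassified
  cat_out[!stranded & !cat_out %in% c("INTERGENIC")] <- "UNCLASSIFIED"

  data.frame(
    transcript_id = tab$transcript_id,
    category = factor(cat_out, levels = categories),
    evidence = vapply(ev, function(g) paste(g, collapse = ","), character(1))
  )
}

#' @rdname classify_transcripts
#' @param t a single-transcript `TranscriptSet` (convenience wrapper)
#' @export
classify_transcript <- function(t, ref, ...) {
  classify_transcripts(t, ref, ...)
}

#' Flag candidates identical to a reference isoform
#'
#' A candidate whose intron chain (scaffold, strand and every intron
#' coordinate) matches a reference transcript's chain is a known
#' isoform, not a novel lncRNA, and is excluded from candidacy before
#' classification. Single-exon chains never match (an empty chain
#' carries no junction evidence).
#'
#' @param ts candidate `TranscriptSet`
#' @param ref `AnnotationIndex`
#' @return logical vector, one per candidate transcript
#' @export
flag_known_transcripts <- function(ts, ref) {
  tab <- tx_table(ts)
  multi <- tab$n_exons >= 2L
  keys <- intron_chain_keys(ts)
  ref_multi <- ref$tx$tx$n_exons >= 2L
  ref_keys <- intron_chain_keys(ref$tx)[ref_multi]
  out <- multi & keys %in% ref_keys
  stats::setNames(out, tab$transcript_id)
}

#' Cluster transcripts into loci by exonic overlap
#'
#' Loci are the connected components of the relation ">=1 bp exon-exon
#' overlap on the same scaffold, any strand". Locus ids are assigned
#' deterministically in order of (scaffold, span start) so the result is
#' invariant to input order.
#'
#' @param ts a `TranscriptSet`
#' @return object of class `locus_clusters`: list with `members`
#'   (data.frame `transcript_id`, `locus_id`) and `loci` (data.frame
#'   `locus_id`, `seqnames`, `start`, `end`, `n_transcripts`)
#' @export
cluster_loci <- function(ts) {
  tab <- tx_table(ts)
  n <- nrow(tab)
  if (n == 0L) {
    return(structure(list(
      members = data.frame(transcript_id = character(), locus_id = character()),
      loci = data.frame(locus_id = character(), seqnames = character(),
                        start = integer(), end = integer(),
                        n_transcripts = integer())), class = "locus_clusters"))
  }
  ord_tab <- tab[order(tab$transcript_id), ]
  idx <- stats::setNames(seq_len(n), ord_tab$transcript_id)

  # union-find over transcripts linked by exon overlap
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }

  ex <- tx_exons(ts)
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  ov <- GenomicRanges::findOverlaps(ex, ignore.strand = TRUE,
                                    drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov)) {
    a <- idx[tid[S4Vectors::queryHits(ov)]]
    b <- idx[tid[S4Vectors::subjectHits(ov)]]
    for (k in seq_along(a)) union_(a[k], b[k])
  }
  root <- vapply(seq_len(n), find, integer(1))

  comp <- split(seq_len(n), root)
  chr <- vapply(comp, function(i) ord_tab$seqnames[i[1L]], character(1))
  st <- vapply(comp, function(i) min(ord_tab$start[i]), numeric(1))
  en <- vapply(comp, function(i) max(ord_tab$end[i]), numeric(1))
  o <- order(chr, st, en)
  locus_ids <- sprintf("LOC_%06d", seq_along(comp))
  members <- data.frame(
    transcript_id = ord_tab$transcript_id[unlist(comp[o], use.names = FALSE)],
    locus_id = rep(locus_ids, lengths(comp)[o])
  )
  loci <- data.frame(locus_id = locus_ids, seqnames = chr[o],
                     start = st[o], end = en[o],
                     n_transcripts = as.integer(lengths(comp)[o]))
  structure(list(members = members, loci = loci), class = "locus_clusters")
}

#' @export
print.locus_clusters <- function(x, ...) {
  cat(sprintf("locus_clusters: %d loci over %d transcripts\n",
              nrow(x$loci), nrow(x$members)))
  invisible(x)
}

#' Category-by-sample count table
#'
#' Cross-tabulates positional categories against per-sample presence
#' (the published table's shape: one row per category plus a total row,
#' one column with overall counts plus one per sample). A transcript is
#' present in a sample when its abundance exceeds `present_above`.
#'
#' @param classes output of [classify_transcripts()]
#' @param expr optional FPKM matrix (rows = transcripts); when NULL only
#'   the overall column is produced
#' @param present_above presence threshold on FPKM (strict >)
#' @return matrix of counts; rows = categories + `"Total"`, first column
#'   `all`, then one column per sample
#' @export
classification_table <- function(classes, expr = NULL, present_above = 0) {
  lev <- levels(classes$category)
  base <- table(factor(classes$category, levels = lev))
  out <- matrix(as.integer(base), ncol = 1,
                dimnames = list(lev, "all"))
  if (!is.null(expr)) {
    common <- intersect(classes$transcript_id, rownames(expr))
    cls <- classes$category[match(common, classes$transcript_id)]
    pres <- expr[common, , drop = FALSE] > present_above
    per <- vapply(colnames(expr), function(s) {
      as.integer(table(factor(cls[pres[, s]], levels = lev)))
    }, integer(length(lev)))
    if (is.null(dim(per))) per <- matrix(per, nrow = length(lev))
    colnames(per) <- colnames(expr)
    out <- cbind(out, per)
  }
  rbind(out, Total = colSums(out))
}
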