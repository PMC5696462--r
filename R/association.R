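#' Overlapping and neighbouring protein-coding genes of lncRNAs
#'
#' For each lncRNA: every reference gene whose span overlaps the lncRNA
#' span (any strand; relation `overlap`, distance 0), plus the nearest
#' non-overlapping gene on each side within `max_report_bp`. The gap
#' distance between two 1-based closed spans is
#' `start(downstream) - end(upstream) - 1`, so a gene ending at 1,000
#' and a lncRNA starting at 1,501 are 500 bp apart. `within_window` is
#' inclusive: a gap of exactly `window_bp` still counts as adjacent.
#'
#' `relation` states where the gene lies relative to the lncRNA along
#' the gene's own transcription direction: `upstream` means following
#' the gene's strand one reaches the lncRNA after the gene.
#'
#' @param lnc lncRNA `TranscriptSet`
#' @param ref an `AnnotationIndex`
#' @param window_bp adjacency window (default 10 kb, inclusive)
#' @param max_report_bp reporting horizon for nearest genes (default
#'   50 kb; the calling window is narrower than what is worth reporting)
#' @return data.frame `lnc_id`, `gene_id`, `seqnames`, `relation`
#'   (`overlap`/`upstream`/`downstream`), `distance_bp`, `within_window`,
#'   `gene_strand`
#' @export
find_neighbors <- function(lnc, ref, window_bp = 10000L, max_report_bp = 50000L) {
  spans <- tx_spans(lnc)
  genes <- ref$genes
  tab <- tx_table(lnc)
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      seqnames = character(), relation = character(),
                      distance_bp = integer(), within_window = logical(),
                      gene_strand = character())
  if (length(spans) == 0L || length(genes) == 0L) return(empty)

  gid <- as.character(S4Vectors::mcols(genes)$gene_id)
  gstr <- as.character(GenomicRanges::strand(genes))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gst <- GenomicRanges::start(genes); gen <- GenomicRanges::end(genes)

  rows <- list()
  add <- function(lnc_id, g, relation, dist, chr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      lnc_id = lnc_id, gene_id = gid[g], seqnames = chr, relation = relation,
      distance_bp = as.integer(dist), within_window = dist <= window_bp,
      gene_strand = gstr[g])
  }

  ov <- GenomicRanges::findOverlaps(spans, genes, ignore.strand = TRUE)
  ov_q <- S4Vectors::queryHits(ov); ov_s <- S4Vectors::subjectHits(ov)
  for (k in seq_along(ov_q)) {
    add(tab$transcript_id[ov_q[k]], ov_s[k], "overlap", 0L, tab$seqnames[ov_q[k]])
  }

  for (i in seq_len(nrow(tab))) {
    on_chr <- which(gchr == tab$seqnames[i])
    if (!length(on_chr)) next
    # strictly left of the lncRNA
    left <- on_chr[gen[on_chr] < tab$start[i]]
    if (length(left)) {
      g <- left[which.max(gen[left])]
      d <- tab$start[i] - gen[g] - 1L
      if (d <= max_report_bp) {
        add(tab$transcript_id[i], g,
            if (gstr[g] == "-") "downstream" else "upstream", d, tab$seqnames[i])
      }
    }
    right <- on_chr[gst[on_chr] > tab$end[i]]
    if (length(right)) {
      g <- right[which.min(gst[right])]
      d <- gst[g] - tab$end[i] - 1L
      if (d <= max_report_bp) {
        add(tab$transcript_id[i], g,
            if (gstr[g] == "-") "upstream" else "downstream", d, tab$seqnames[i])
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$lnc_id, out$distance_bp, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Attach co-expression statistics to neighbour links
#'
#' Delegates to [pearson_coexpression()] for every (lncRNA, gene) pair
#' that has expression profiles in the matrix; links whose members are
#' absent are kept with NA statistics and a warning is emitted.
#'
#' @param links output of [find_neighbors()]
#' @param mat FPKM matrix containing lncRNA and gene profiles
#' @param strong_cut |r| threshold for the strong label
#' @param log_scale passed to [pearson_coexpression()]
#' @return `links` with added columns `r`, `p_value`, `strong`
#' @export
annotate_links <- function(links, mat, strong_cut = 0.8, log_scale = FALSE) {
  if (nrow(links) == 0L) {
    links$r <- numeric(0); links$p_value <- numeric(0); links$strong <- logical(0)
    return(links)
  }
  co <- pearson_coexpression(mat, links[, c("lnc_id", "gene_id")],
                             strong_cut = strong_cut, log_scale = log_scale)
  if (any(co$missing)) {
    warning(sum(co$missing), " link(s) with members absent from the ",
            "expression matrix left unannotated")
  }
  links$r <- co$r
  links$p_value <- co$p_value
  links$strong <- co$strong
  links
}

#' Overlap geometry between lncRNAs and reference genes
#'
#' For every lncRNA whose span intersects a gene span: the overlap
#' length (1-based closed intersection size), whether the overlap
#' touches annotated exons of that gene (`part` = `exon`) or only
#' intronic sequence (`intron`; `unresolved` when the gene carries no
#' exon-level annotation), and the relative orientation.
#'
#' @param lnc lncRNA `TranscriptSet`
#' @param ref `AnnotationIndex`
#' @return data.frame `lnc_id`, `gene_id`, `overlap_bp`, `part`,
#'   `orientation` (`sense`/`antisense`/`unknown`)
#' @export
overlap_report <- function(lnc, ref) {
  spans <- tx_spans(lnc)
  genes <- ref$genes
  ov <- GenomicRanges::findOverlaps(spans, genes, ignore.strand = TRUE)
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      overlap_bp = integer(), part = character(),
                      orientation = character())
  if (length(ov) == 0L) return(empty)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter_st <- pmax(GenomicRanges::start(spans)[q], GenomicRanges::start(genes)[s])
  inter_en <- pmin(GenomicRanges::end(spans)[q], GenomicRanges::end(genes)[s])
  gid <- as.character(S4Vectors::mcols(genes)$gene_id)[s]
  lid <- names(spans)[q]

  ex_gid <- as.character(S4Vectors::mcols(ref$exons)$gene_id)
  lnc_ex <- tx_exons(lnc)
  lnc_tid <- as.character(S4Vectors::mcols(lnc_ex)$transcript_id)
  part <- vapply(seq_along(q), function(k) {
    ge <- ref$exons[ex_gid == gid[k]]
    if (length(ge) == 0L) return("unresolved")
    le <- lnc_ex[lnc_tid == lid[k]]
    if (length(GenomicRanges::findOverlaps(le, ge, ignore.strand = TRUE)) > 0L)
      "exon" else "intron"
  }, character(1))

  lstr <- as.character(GenomicRanges::strand(spans))[q]
  gstr <- as.character(GenomicRanges::strand(genes))[s]
  orientation <- ifelse(lstr %in% c("+", "-") & gstr %in% c("+", "-"),
                        ifelse(lstr == gstr, "sense", "antisense"), "unknown")

  out <- data.frame(lnc_id = lid, gene_id = gid,
                    overlap_bp = as.integer(inter_en - inter_st + 1L),
                    part = part, orientation = orientation)
  out <- out[order(out$lnc_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}
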