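#' Transcript model containers
#'
#' A `TranscriptSet` holds a collection of stranded, multi-exon transcript
#' models as a single exon-level [GenomicRanges::GRanges] (metadata columns
#' `transcript_id` and `gene_id`) together with a per-transcript summary
#' table. All coordinates are 1-based and closed, the GRanges convention,
#' so GTF import/export is the identity on coordinates.
#'
#' @param exons a `GRanges` of exons with metadata columns `transcript_id`
#'   and `gene_id`. Exons of one transcript must lie on a single scaffold
#'   and strand and must not overlap one another.
#' @return an object of class `TranscriptSet` with elements `exons`
#'   (sorted exon `GRanges`) and `tx` (per-transcript `data.frame` with
#'   columns `transcript_id`, `gene_id`, `seqnames`, `strand`, `n_exons`,
#'   `spliced_len`, `start`, `end`).
#' @export
transcript_set <- function(exons) {
  stopifnot(methods::is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (!all(c("transcript_id", "gene_id") %in% colnames(mc))) {
    stop("exon GRanges needs 'transcript_id' and 'gene_id' metadata columns")
  }
  tid <- as.character(mc$transcript_id)
  if (length(exons) == 0L) {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     seqnames = character(), strand = character(),
                     n_exons = integer(), spliced_len = integer(),
                     start = integer(), end = integer())
    return(structure(list(exons = exons, tx = tx), class = "TranscriptSet"))
  }
  ord <- order(tid, GenomicRanges::start(exons))
  exons <- exons[ord]
  tid <- tid[ord]

  chr <- as.character(GenomicRanges::seqnames(exons))
  str <- as.character(GenomicRanges::strand(exons))
  by_tx <- split(seq_along(exons), tid)

  bad_chr <- vapply(by_tx, function(i) length(unique(chr[i])) > 1L, logical(1))
  if (any(bad_chr)) {
    stop("transcript(s) with exons on multiple scaffolds: ",
         paste(names(by_tx)[bad_chr], collapse = ", "))
  }
  bad_str <- vapply(by_tx, function(i) length(unique(str[i])) > 1L, logical(1))
  if (any(bad_str)) {
    stop("transcript(s) with exons on multiple strands: ",
         paste(names(by_tx)[bad_str], collapse = ", "))
  }
  st <- GenomicRanges::start(exons); en <- GenomicRanges::end(exons)
  bad_ovl <- vapply(by_tx, function(i) {
    if (length(i) < 2L) return(FALSE)
    any(st[i][-1L] <= en[i][-length(i)])
  }, logical(1))
  if (any(bad_ovl)) {
    stop("transcript(s) with overlapping or unsorted exons: ",
         paste(names(by_tx)[bad_ovl], collapse = ", "))
  }

  first <- vapply(by_tx, `[`, integer(1), 1L)
  tx <- data.frame(
    transcript_id = names(by_tx),
    gene_id = as.character(mc$gene_id[ord])[first],
    seqnames = chr[first],
    strand = str[first],
    n_exons = lengths(by_tx),
    spliced_len = vapply(by_tx, function(i) sum(en[i] - st[i] + 1L), numeric(1)),
    start = vapply(by_tx, function(i) min(st[i]), numeric(1)),
    end = vapply(by_tx, function(i) max(en[i]), numeric(1)),
    row.names = NULL
  )
  structure(list(exons = exons, tx = tx), class = "TranscriptSet")
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("TranscriptSet: %d transcripts, %d exons on %d scaffold(s)\n",
              nrow(x$tx), length(x$exons), length(unique(x$tx$seqnames))))
  invisible(x)
}

#' @export
length.TranscriptSet <- function(x) nrow(x$tx)

#' Accessors for TranscriptSet
#'
#' `tx_ids()` returns the transcript identifiers, `tx_table()` the
#' per-transcript summary, `tx_exons()` the exon `GRanges`,
#' `tx_spans()` one genomic span per transcript and `tx_introns()` the
#' derived introns (gaps between consecutive exons, so a transcript with
#' k exons contributes k - 1 introns).
#'
#' @param x a `TranscriptSet`
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
tx_ids <- function(x) x$tx$transcript_id

#' @rdname transcript-accessors
#' @export
tx_table <- function(x) x$tx

#' @rdname transcript-accessors
#' @export
tx_exons <- function(x) x$exons

#' @rdname transcript-accessors
#' @export
tx_spans <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$tx$seqnames,
    ranges = IRanges::IRanges(start = x$tx$start, end = x$tx$end),
    strand = x$tx$strand
  )
  S4Vectors::mcols(gr)$transcript_id <- x$tx$transcript_id
  S4Vectors::mcols(gr)$gene_id <- x$tx$gene_id
  names(gr) <- x$tx$transcript_id
  gr
}

#' @rdname transcript-accessors
#' @export
tx_introns <- function(x) {
  ex <- x$exons
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  gid <- as.character(S4Vectors::mcols(ex)$gene_id)
  n <- length(ex)
  if (n == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$transcript_id <- character()
    S4Vectors::mcols(out)$gene_id <- character()
    return(out)
  }
  # exons are sorted by (transcript, start); an intron exists wherever two
  # consecutive rows belong to the same transcript
  same <- tid[-1L] == tid[-n]
  if (!any(same)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$transcript_id <- character()
    S4Vectors::mcols(out)$gene_id <- character()
    return(out)
  }
  i <- which(same)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex)[i],
    ranges = IRanges::IRanges(start = GenomicRanges::end(ex)[i] + 1L,
                              end = GenomicRanges::start(ex)[i + 1L] - 1L),
    strand = GenomicRanges::strand(ex)[i]
  )
  S4Vectors::mcols(out)$transcript_id <- tid[i]
  S4Vectors::mcols(out)$gene_id <- gid[i]
  out
}

#' Subset a TranscriptSet by transcript id
#'
#' @param x a `TranscriptSet`
#' @param ids character vector of transcript ids to keep
#' @return the reduced `TranscriptSet`
#' @export
tx_subset <- function(x, ids) {
  keep <- as.character(S4Vectors::mcols(x$exons)$transcript_id) %in% ids
  transcript_set(x$exons[keep])
}

#' Intron-chain keys
#'
#' One string per transcript encoding scaffold, strand and the exact
#' coordinates of every intron; two transcripts are the same isoform iff
#' their keys are equal. Single-exon transcripts get an empty chain.
#'
#' @param x a `TranscriptSet`
#' @return named character vector, one element per transcript
#' @export
intron_chain_keys <- function(x) {
  intr <- tx_introns(x)
  tid <- as.character(S4Vectors::mcols(intr)$transcript_id)
  part <- paste0(GenomicRanges::start(intr), "-", GenomicRanges::end(intr))
  chains <- vapply(split(part, tid), paste, character(1), collapse = ";")
  out <- stats::setNames(
    paste0(x$tx$seqnames, ":", x$tx$strand, ":", ""),
    x$tx$transcript_id
  )
  hit <- match(names(chains), names(out))
  out[hit] <- paste0(x$tx$seqnames[hit], ":", x$tx$strand[hit], ":", chains)
  out
}

#' Build a queryable reference annotation
#'
#' Wraps a reference `TranscriptSet` with gene-level spans and derived
#' introns so that classification and neighbour searches can query genes,
#' exons and introns directly.
#'
#' @param ts reference `TranscriptSet`
#' @param biotype single string or vector (one per gene) of gene biotypes
#' @return an `AnnotationIndex`: list with elements `tx`, `genes`
#'   (one `GRanges` span per gene, metadata `gene_id`, `biotype`),
#'   `exons`, `introns`
#' @export
annotation_index <- function(ts, biotype = "protein_coding") {
  stopifnot(inherits(ts, "TranscriptSet"))
  tab <- ts$tx
  by_gene <- split(seq_len(nrow(tab)), tab$gene_id)
  chr <- vapply(by_gene, function(i) tab$seqnames[i[1L]], character(1))
  str <- vapply(by_gene, function(i) tab$strand[i[1L]], character(1))
  gstart <- vapply(by_gene, function(i) min(tab$start[i]), numeric(1))
  gend <- vapply(by_gene, function(i) max(tab$end[i]), numeric(1))
  genes <- GenomicRanges::GRanges(chr, IRanges::IRanges(gstart, gend), strand = str)
  S4Vectors::mcols(genes)$gene_id <- names(by_gene)
  if (length(biotype) == 1L) biotype <- rep(biotype, length(genes))
  S4Vectors::mcols(genes)$biotype <- biotype
  names(genes) <- names(by_gene)
  genes <- genes[order(chr, gstart)]
  structure(list(tx = ts, genes = genes, exons = tx_exons(ts),
                 introns = tx_introns(ts)),
            class = "AnnotationIndex")
}

#' @export
print.AnnotationIndex <- function(x, ...) {
  cat(sprintf("AnnotationIndex: %d genes, %d transcripts, %d exons\n",
              length(x$genes), nrow(x$tx$tx), length(x$exons)))
  invisible(x)
}
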