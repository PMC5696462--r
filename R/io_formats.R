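#' Read transcript models from GTF/GFF3
#'
#' Exon features are grouped by `transcript_id` into transcript models.
#' Coordinates stay 1-based closed (the GTF and GRanges convention).
#' For `kind = "reference"` the models are additionally wrapped in an
#' [annotation_index()] so genes, exons and introns can be queried.
#'
#' @param path GTF (2.2 dialect) or GFF3 file; format chosen from the
#'   extension, override with `format`
#' @param kind `"candidate"` returns a `TranscriptSet`; `"reference"`
#'   returns an `AnnotationIndex`
#' @param format passed to [rtracklayer::import()] ("gtf" or "gff3")
#' @return `TranscriptSet` or `AnnotationIndex`
#' @export
read_gtf <- function(path, kind = c("candidate", "reference"), format = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  mc <- S4Vectors::mcols(gr)
  tid <- mc$transcript_id
  if (is.null(tid)) {
    # GFF3 dialect: exon Parent points at the mRNA/transcript feature
    tid <- as.character(mc$Parent)
  }
  if (is.null(tid) || anyNA(tid)) {
    stop("exon feature(s) without transcript_id/Parent attribute in ", path)
  }
  gid <- mc$gene_id
  if (is.null(gid)) gid <- tid
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$transcript_id <- as.character(tid)
  S4Vectors::mcols(out)$gene_id <- as.character(gid)
  ts <- transcript_set(out)
  if (kind == "reference") annotation_index(ts) else ts
}

#' Write a TranscriptSet as GTF
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes; [read_gtf()] of the result reproduces the model set exactly.
#'
#' @param ts a `TranscriptSet`
#' @param path output file
#' @param source value for the GTF source column
#' @return `path`, invisibly
#' @export
write_gtf <- function(ts, path, source = "lncscout") {
  gr <- tx_exons(ts)
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- "exon"
  # stable output order: scaffold, transcript, position
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               S4Vectors::mcols(gr)$transcript_id,
               GenomicRanges::start(gr))
  rtracklayer::export(gr[ord], path, format = "gtf")
  invisible(path)
}

#' Read/write transcript sequences (FASTA)
#'
#' Sequences are upper-cased and RNA `U` is normalised to `T`.
#' Duplicate record ids are an error.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "T", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of nucleotide sequences
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read an FPKM expression matrix from TSV
#'
#' First column transcript id, remaining columns one per sample; `#`
#' comment lines are skipped. Values must be numeric and non-negative.
#'
#' @param path tab-separated file
#' @return numeric matrix, rows = transcripts, columns = samples
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric expression value at row %d (id %s), column '%s'",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]]))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing expression value at row %d (id %s), column '%s'",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop(sprintf("negative FPKM at row %d (id %s), column '%s'",
                 bad[1L, 1L], ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param mat numeric matrix with row and column names
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.hit_kinds <- c("protein_db", "domain", "ncrna_family", "coding_potential")

#' Homology / coding-potential hit tables
#'
#' A hit table is a plain TSV with columns `query_id`, `subject`,
#' `evalue`, `score` and a declared `kind` — one of `protein_db`
#' (protein-database search), `domain` (protein-domain scan),
#' `ncrna_family` (structured-ncRNA family scan) or `coding_potential`
#' (a scalar classifier score per transcript, carried in `score`).
#'
#' @param path TSV file with a header
#' @param kind expected table kind; a `kind` column in the file must agree
#' @return data.frame of class `hit_table` with attribute `kind`
#' @export
read_hit_table <- function(path, kind = c("protein_db", "domain",
                                          "ncrna_family", "coding_potential")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  hit_table(df, kind)
}

#' @rdname read_hit_table
#' @param df data.frame with at least `query_id`; `subject`, `evalue`,
#'   `score` filled with defaults when absent
#' @export
hit_table <- function(df, kind) {
  kind <- match.arg(kind, .hit_kinds)
  if (!"query_id" %in% names(df)) stop("hit table needs a 'query_id' column")
  if (!"subject" %in% names(df)) df$subject <- NA_character_
  if (!"evalue" %in% names(df)) df$evalue <- 0
  if (!"score" %in% names(df)) df$score <- NA_real_
  if ("kind" %in% names(df) && nrow(df) > 0L && !all(df$kind == kind)) {
    stop("hit table declares kind '", df$kind[1L], "' but '", kind, "' expected")
  }
  df$evalue <- as.numeric(df$evalue)
  if (any(!is.na(df$evalue) & df$evalue < 0)) stop("negative e-value in hit table")
  out <- df[, c("query_id", "subject", "evalue", "score")]
  class(out) <- c("hit_table", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @rdname read_hit_table
#' @export
empty_hit_table <- function(kind) {
  hit_table(data.frame(query_id = character(), subject = character(),
                       evalue = numeric(), score = numeric()), kind)
}

#' Adapter for BLAST tabular output (-outfmt 6)
#'
#' Maps the 12 standard columns onto the hit-table shape (qseqid ->
#' query_id, sseqid -> subject, evalue, bitscore -> score).
#'
#' @param path BLAST outfmt-6 file (no header)
#' @param kind hit-table kind to assign
#' @return `hit_table`
#' @export
read_blast6 <- function(path, kind = "protein_db") {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(ncol(df), 12L))] <- cols[seq_len(min(ncol(df), 12L))]
  hit_table(data.frame(query_id = df$qseqid, subject = df$sseqid,
                       evalue = df$evalue, score = df$bitscore), kind)
}

#' @rdname read_hit_table
#' @param x a `hit_table`
#' @export
write_hit_table <- function(x, path) {
  out <- as.data.frame(x)
  out$kind <- attr(x, "kind")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates the exon sequences of each transcript in genomic order and
#' reverse-complements the result for reverse-strand transcripts.
#'
#' @param genome named character vector (or `DNAStringSet`) of scaffold
#'   sequences
#' @param ts a `TranscriptSet`
#' @return named character vector of spliced sequences
#' @export
extract_spliced <- function(genome, ts) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  tab <- ts$tx
  ex <- tx_exons(ts)
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  chr <- as.character(GenomicRanges::seqnames(ex))
  missing <- setdiff(unique(chr), names(genome))
  if (length(missing)) stop("scaffold(s) absent from genome: ",
                            paste(missing, collapse = ", "))
  pieces <- substring(genome[chr], GenomicRanges::start(ex), GenomicRanges::end(ex))
  spliced <- vapply(split(pieces, tid), paste, character(1), collapse = "")
  spliced <- spliced[tab$transcript_id]
  rev <- tab$strand == "-"
  if (any(rev)) {
    spliced[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(spliced[rev])))
  }
  stats::setNames(spliced, tab$transcript_id)
}
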