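#' Six-frame open reading frame scanning
#'
#' An ORF is an ATG-initiated codon run ending at the first in-frame stop
#' (TAA/TAG/TGA, included in the length) — the start-to-stop definition
#' that matches the ">100 amino acids" convention used to draw the line
#' between coding transcripts and lncRNAs. Within a frame, the first ATG
#' after the previous stop opens the next ORF; ATGs nested inside a
#' reported ORF are not reported separately. A stop-to-stop mode is
#' available for sensitivity analysis. Codons containing `N` match
#' neither ATG nor a stop.
#'
#' Frames 1-3 scan the forward sequence at offsets 0-2; frames 4-6 scan
#' the reverse complement at the same offsets. Reported `start`/`end` are
#' 1-based inclusive positions on the frame's own sequence (i.e. on the
#' reverse complement for frames 4-6).
#'
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive;
#'   U accepted and read as T)
#' @param both_strands scan frames 4-6 as well (default TRUE)
#' @param include_open_ended also report ATG runs that hit the sequence
#'   end without an in-frame stop (default TRUE); such hits are flagged
#'   `open_ended` and truncated at the last complete codon
#' @param mode `"start_stop"` (default) or `"stop_stop"` (maximal codon
#'   runs delimited by stops, no ATG requirement)
#' @return data.frame with columns `frame` (1-6), `start`, `end`,
#'   `length_nt`, `open_ended`, sorted by decreasing length
#' @export
find_orfs <- function(sequence, both_strands = TRUE, include_open_ended = TRUE,
                      mode = c("start_stop", "stop_stop")) {
  mode <- match.arg(mode)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  if (nchar(s) > 0L && grepl("[^ACGTN]", s)) {
    stop("invalid characters in sequence (allowed: A, C, G, T, N, U)")
  }
  empty <- data.frame(frame = integer(), start = integer(), end = integer(),
                      length_nt = integer(), open_ended = logical())
  if (nchar(s) < 3L) return(empty)

  frames <- 1:3
  rc <- NULL
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    frames <- 1:6
  }
  out <- lapply(frames, function(f) {
    fs <- if (f <= 3L) substring(s, f) else substring(rc, f - 3L)
    hits <- .scan_frame(fs, include_open_ended, mode)
    if (nrow(hits)) hits$frame <- f
    hits
  })
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0L])
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(-out$length_nt, out$frame, out$start),
             c("frame", "start", "end", "length_nt", "open_ended")]
  rownames(out) <- NULL
  out
}

# scan one frame-shifted sequence; returns start/end (1-based, on the
# frame sequence), length and open-ended flag
.scan_frame <- function(fs, include_open_ended, mode) {
  n <- nchar(fs)
  k <- n %/% 3L
  none <- data.frame(start = integer(), end = integer(),
                     length_nt = integer(), open_ended = logical())
  if (k == 0L) return(none)
  codons <- substring(fs, 3L * (0:(k - 1L)) + 1L, 3L * (1:k))
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  stops <- which(is_stop)

  if (mode == "stop_stop") {
    st <- integer(); en <- integer(); op <- logical()
    lo <- c(0L, stops)
    for (b in seq_along(lo)) {
      first <- lo[b] + 1L
      nxt <- stops[stops >= first]
      if (length(nxt)) {
        st <- c(st, first); en <- c(en, nxt[1L]); op <- c(op, FALSE)
      } else if (first <= k && include_open_ended) {
        st <- c(st, first); en <- c(en, k); op <- c(op, TRUE)
      }
    }
    keep <- en - st + 1L >= 1L
    return(data.frame(start = 3L * (st[keep] - 1L) + 1L, end = 3L * en[keep],
                      length_nt = 3L * (en[keep] - st[keep] + 1L),
                      open_ended = op[keep]))
  }

  starts <- which(codons == "ATG")
  if (length(starts) == 0L) return(none)
  st <- integer(); en <- integer(); op <- logical()
  pos <- 1L
  repeat {
    cand <- starts[starts >= pos]
    if (length(cand) == 0L) break
    i <- cand[1L]
    nxt <- stops[stops > i]
    if (length(nxt)) {
      j <- nxt[1L]
      st <- c(st, i); en <- c(en, j); op <- c(op, FALSE)
      pos <- j + 1L
    } else {
      if (include_open_ended) {
        st <- c(st, i); en <- c(en, k); op <- c(op, TRUE)
      }
      break
    }
  }
  if (length(st) == 0L) return(none)
  data.frame(start = 3L * (st - 1L) + 1L, end = 3L * en,
             length_nt = 3L * (en - st + 1L), open_ended = op)
}

#' Longest ORF per transcript
#'
#' @param seqs named character vector of transcript sequences
#' @inheritParams find_orfs
#' @return data.frame `transcript_id`, `longest_orf_nt` (0 when no ORF),
#'   `frame`, `open_ended`
#' @export
longest_orfs <- function(seqs, both_strands = TRUE, include_open_ended = TRUE,
                         mode = "start_stop") {
  stopifnot(!is.null(names(seqs)))
  rows <- lapply(seq_along(seqs), function(i) {
    o <- find_orfs(seqs[[i]], both_strands, include_open_ended, mode)
    if (nrow(o) == 0L) {
      data.frame(transcript_id = names(seqs)[i], longest_orf_nt = 0L,
                 frame = NA_integer_, open_ended = NA)
    } else {
      data.frame(transcript_id = names(seqs)[i], longest_orf_nt = o$length_nt[1L],
                 frame = o$frame[1L], open_ended = o$open_ended[1L])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ORF-length coding filter
#'
#' Removes a transcript iff its longest ORF is strictly longer than
#' `max_orf_nt` (default 300 nt, i.e. 100 codons including the stop):
#' transcripts whose longest ORF is exactly 300 nt are kept.
#'
#' @param seqs named character vector of transcript sequences
#' @param max_orf_nt removal threshold in nucleotides (strict >)
#' @inheritParams find_orfs
#' @return list with `kept` (ids), `removed` (ids) and `report`
#'   (data.frame of removed ids with the offending ORF length and frame)
#' @export
orf_filter <- function(seqs, max_orf_nt = 300L, both_strands = TRUE,
                       include_open_ended = TRUE, mode = "start_stop") {
  stopifnot(max_orf_nt > 0)
  lo <- longest_orfs(seqs, both_strands, include_open_ended, mode)
  removed <- lo$longest_orf_nt > max_orf_nt
  list(kept = lo$transcript_id[!removed],
       removed = lo$transcript_id[removed],
       report = lo[removed, , drop = FALSE])
}
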