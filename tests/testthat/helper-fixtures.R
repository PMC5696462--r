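# shared builders and independent oracles for the test suite

# build a TranscriptSet from a list of transcripts:
#   list(t1 = list(chr = "s1", strand = "+", exons = list(c(1, 100), c(201, 300))))
make_ts <- function(spec, gene_ids = NULL) {
  rows <- do.call(rbind, lapply(names(spec), function(id) {
    t <- spec[[id]]
    ex <- do.call(rbind, t$exons)
    data.frame(seqnames = t$chr, start = ex[, 1], end = ex[, 2],
               strand = t$strand, transcript_id = id,
               gene_id = if (!is.null(gene_ids)) gene_ids[[id]] else
                 if (!is.null(t$gene)) t$gene else paste0("g_", id))
  }))
  gr <- GenomicRanges::GRanges(rows$seqnames,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  transcript_set(gr)
}

make_ref <- function(spec, gene_ids = NULL) {
  annotation_index(make_ts(spec, gene_ids))
}

# memoised default fixture shared across test files
.fixture_cache <- new.env(parent = emptyenv())
get_default_fixture <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- default_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}

# ---- independent ORF oracle: enumerate every ATG, walk codon by codon ----
oracle_orfs <- function(seq, both_strands = TRUE, include_open_ended = TRUE) {
  seq <- toupper(seq)
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  frame_hits <- function(fs) {
    n <- nchar(fs)
    hits <- list()
    # every ATG with its first downstream in-frame stop
    for (p in seq_len(max(0, n - 2))) {
      if (substr(fs, p, p + 2) != "ATG") next
      q <- p
      stop_at <- NA
      while (q + 2 <= n) {
        cod <- substr(fs, q, q + 2)
        if (cod %in% c("TAA", "TAG", "TGA") && q > p) { stop_at <- q; break }
        q <- q + 3
      }
      if (!is.na(stop_at)) {
        hits[[length(hits) + 1]] <- c(start = p, end = stop_at + 2, open = 0)
      } else if (include_open_ended) {
        last <- p + 3 * ((n - p + 1) %/% 3) - 1
        hits[[length(hits) + 1]] <- c(start = p, end = last, open = 1)
      }
    }
    if (!length(hits)) return(NULL)
    h <- as.data.frame(do.call(rbind, hits))
    # maximality: per frame offset, keep the earliest ATG per stop
    h$offset <- (h$start - 1) %% 3
    keep <- do.call(rbind, lapply(split(h, list(h$offset, h$end), drop = TRUE),
                                  function(g) g[which.min(g$start), ]))
    keep
  }
  out <- list()
  for (f in 1:3) {
    fs <- substring(seq, f)
    h <- frame_hits(fs)
    if (!is.null(h)) {
      h <- h[h$offset == 0, , drop = FALSE]
      if (nrow(h)) out[[length(out) + 1]] <-
          data.frame(frame = f, start = h$start, end = h$end,
                     length_nt = h$end - h$start + 1, open_ended = h$open == 1)
    }
  }
  if (both_strands) {
    rc <- revcomp(seq)
    for (f in 4:6) {
      fs <- substring(rc, f - 3)
      h <- frame_hits(fs)
      if (!is.null(h)) {
        h <- h[h$offset == 0, , drop = FALSE]
        if (nrow(h)) out[[length(out) + 1]] <-
            data.frame(frame = f, start = h$start, end = h$end,
                       length_nt = h$end - h$start + 1, open_ended = h$open == 1)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_nt = integer(), open_ended = logical()))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$length_nt, res$frame, res$start), ]
  rownames(res) <- NULL
  res
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# ---- naive all-pairs positional classifier ----
oracle_classify <- function(ts, ref) {
  tab <- tx_table(ts)
  ex <- tx_exons(ts)
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  intr <- tx_introns(ts)
  itid <- as.character(S4Vectors::mcols(intr)$transcript_id)
  rtab <- tx_table(ref$tx)
  rex <- ref$exons
  rex_tid <- as.character(S4Vectors::mcols(rex)$transcript_id)
  rintr <- ref$introns
  rintr_tid <- as.character(S4Vectors::mcols(rintr)$transcript_id)
  genes <- ref$genes

  olap <- function(s1, e1, s2, e2) max(s1, s2) <= min(e1, e2)

  vapply(seq_len(nrow(tab)), function(i) {
    id <- tab$transcript_id[i]
    chr <- tab$seqnames[i]; str <- tab$strand[i]
    stranded <- str %in% c("+", "-")
    my_ex <- which(tid == id)
    my_in <- which(itid == id)

    if (stranded) {
      # junction: identical intron, same strand
      for (k in my_in) {
        same <- which(as.character(GenomicRanges::seqnames(rintr)) == chr &
                      as.character(GenomicRanges::strand(rintr)) == str &
                      GenomicRanges::start(rintr) == GenomicRanges::start(intr)[k] &
                      GenomicRanges::end(rintr) == GenomicRanges::end(intr)[k])
        if (length(same)) return("JUNCTION_SHARE")
      }
      # exon-exon overlap, sense then antisense
      for (sense in c(TRUE, FALSE)) {
        for (k in my_ex) {
          hit <- which(as.character(GenomicRanges::seqnames(rex)) == chr &
                       (as.character(GenomicRanges::strand(rex)) == str) == sense)
          for (j in hit) {
            if (olap(GenomicRanges::start(ex)[k], GenomicRanges::end(ex)[k],
                     GenomicRanges::start(rex)[j], GenomicRanges::end(rex)[j])) {
              return(if (sense) "EXONIC_SENSE" else "EXONIC_ANTISENSE")
            }
          }
        }
      }
      # containment of the whole candidate in one reference intron
      for (sense in c(TRUE, FALSE)) {
        for (j in which(as.character(GenomicRanges::seqnames(rintr)) == chr &
                        (as.character(GenomicRanges::strand(rintr)) == str) == sense)) {
          if (tab$start[i] >= GenomicRanges::start(rintr)[j] &&
              tab$end[i] <= GenomicRanges::end(rintr)[j]) {
            return(if (sense) "INTRONIC_SENSE" else "INTRONIC_ANTISENSE")
          }
        }
      }
    }
    # intergenic: no gene-span overlap at all
    any_gene <- FALSE
    for (j in which(as.character(GenomicRanges::seqnames(genes)) == chr)) {
      if (olap(tab$start[i], tab$end[i],
               GenomicRanges::start(genes)[j], GenomicRanges::end(genes)[j])) {
        any_gene <- TRUE; break
      }
    }
    if (!any_gene) return("INTERGENIC")
    "UNCLASSIFIED"
  }, character(1))
}

# random candidate transcripts over a genome layout (for oracle comparison)
random_candidates <- function(annotation, scaffold_len, n = 100,
                              strands = c("+", "-", "*")) {
  scafs <- unique(as.character(GenomicRanges::seqnames(annotation$genes)))
  rows <- list()
  for (i in seq_len(n)) {
    chr <- sample(scafs, 1)
    ne <- sample(1:4, 1)
    widths <- sample(80:400, ne, replace = TRUE)
    gaps <- if (ne > 1) sample(50:3000, ne - 1, replace = TRUE) else integer(0)
    total <- sum(widths) + sum(gaps)
    st0 <- sample.int(scaffold_len - total - 1, 1)
    starts <- st0 + cumsum(c(0, widths[-ne] + gaps))
    rows[[i]] <- data.frame(seqnames = chr, start = starts,
                            end = starts + widths - 1,
                            strand = sample(strands, 1),
                            transcript_id = sprintf("rnd_%04d", i),
                            gene_id = sprintf("rndg_%04d", i))
  }
  ex <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(ex$seqnames, IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  transcript_set(gr)
}

# ---- brute-force nearest-gene scan ----
oracle_neighbors <- function(lnc, ref, window_bp = 10000, max_report_bp = 50000) {
  tab <- tx_table(lnc)
  genes <- ref$genes
  gid <- as.character(S4Vectors::mcols(genes)$gene_id)
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    best_l <- NULL; best_r <- NULL
    for (j in seq_along(genes)) {
      if (as.character(GenomicRanges::seqnames(genes))[j] != tab$seqnames[i]) next
      gs <- GenomicRanges::start(genes)[j]; ge <- GenomicRanges::end(genes)[j]
      if (max(gs, tab$start[i]) <= min(ge, tab$end[i])) {
        rows[[length(rows) + 1]] <- data.frame(
          lnc_id = tab$transcript_id[i], gene_id = gid[j], distance_bp = 0L)
      } else if (ge < tab$start[i]) {
        d <- tab$start[i] - ge - 1
        if (is.null(best_l) || d < best_l$d) best_l <- list(j = j, d = d)
      } else {
        d <- gs - tab$end[i] - 1
        if (is.null(best_r) || d < best_r$d) best_r <- list(j = j, d = d)
      }
    }
    for (b in list(best_l, best_r)) {
      if (!is.null(b) && b$d <= max_report_bp) {
        rows[[length(rows) + 1]] <- data.frame(
          lnc_id = tab$transcript_id[i], gene_id = gid[b$j],
          distance_bp = as.integer(b$d))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$lnc_id, out$distance_bp, out$gene_id), ]
}
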