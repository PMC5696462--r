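#' Structural summary of a lncRNA catalogue
#'
#' Computes the gene-structure descriptors usually reported for a lncRNA
#' set: the exon-count histogram, spliced transcript-length summaries
#' for lncRNAs and (optionally) protein-coding transcripts, the number
#' of lncRNA loci per scaffold, and the alternative-splicing fraction —
#' the proportion of loci carrying >= 2 distinct isoforms (distinct
#' intron chains).
#'
#' @param lnc lncRNA `TranscriptSet`
#' @param coding optional protein-coding `TranscriptSet` for the length
#'   comparison
#' @param loci optional `locus_clusters` for `lnc`; computed with
#'   [cluster_loci()] when NULL
#' @return list of class `structure_summary` with elements
#'   `exon_count_hist` (data.frame `n_exons`, `n_transcripts`,
#'   `fraction`), `length_summary` (data.frame per biotype with mean and
#'   median spliced length and genomic span), `scaffold_hist`
#'   (data.frame `seqnames`, `n_loci`), `as_fraction` (scalar in [0,1],
#'   NA for an empty catalogue) and `n_transcripts`, `n_loci`
#' @export
summarize_structure <- function(lnc, coding = NULL, loci = NULL) {
  tab <- tx_table(lnc)
  if (is.null(loci)) loci <- cluster_loci(lnc)

  if (nrow(tab) == 0L) {
    return(structure(list(
      exon_count_hist = data.frame(n_exons = integer(), n_transcripts = integer(),
                                   fraction = numeric()),
      length_summary = data.frame(biotype = character(), n = integer(),
                                  mean_spliced_len = numeric(),
                                  median_spliced_len = numeric(),
                                  mean_span = numeric()),
      scaffold_hist = data.frame(seqnames = character(), n_loci = integer()),
      as_fraction = NA_real_, n_transcripts = 0L, n_loci = 0L),
      class = "structure_summary"))
  }

  h <- table(tab$n_exons)
  exon_hist <- data.frame(n_exons = as.integer(names(h)),
                          n_transcripts = as.integer(h),
                          fraction = as.numeric(h) / nrow(tab))

  len_row <- function(t, biotype) data.frame(
    biotype = biotype, n = nrow(t),
    mean_spliced_len = mean(t$spliced_len),
    median_spliced_len = stats::median(t$spliced_len),
    mean_span = mean(t$end - t$start + 1))
  lens <- len_row(tab, "lncRNA")
  if (!is.null(coding) && length(coding) > 0L) {
    lens <- rbind(lens, len_row(tx_table(coding), "protein_coding"))
  }

  sc <- table(loci$loci$seqnames)
  scaffold_hist <- data.frame(seqnames = names(sc), n_loci = as.integer(sc))

  iso <- isoform_report(lnc, loci)
  as_fraction <- mean(iso$n_isoforms >= 2L)

  structure(list(exon_count_hist = exon_hist, length_summary = lens,
                 scaffold_hist = scaffold_hist, as_fraction = as_fraction,
                 n_transcripts = nrow(tab), n_loci = nrow(loci$loci)),
            class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf("structure_summary: %d transcripts in %d loci; AS fraction %.3f\n",
              x$n_transcripts, x$n_loci,
              if (is.na(x$as_fraction)) NA else x$as_fraction))
  invisible(x)
}

#' Isoform counts per locus
#'
#' Two transcripts are the same isoform iff their intron chains (exact
#' intron coordinates on one scaffold and strand) coincide, so ragged
#' transcript ends do not inflate the count; all single-exon transcripts
#' of one locus count as one isoform.
#'
#' @param ts `TranscriptSet`
#' @param loci `locus_clusters` for `ts` (computed when NULL)
#' @return data.frame `locus_id`, `n_transcripts`, `n_isoforms`, sorted
#'   by decreasing `n_isoforms`
#' @export
isoform_report <- function(ts, loci = NULL) {
  if (is.null(loci)) loci <- cluster_loci(ts)
  keys <- intron_chain_keys(ts)
  mem <- loci$members
  by <- split(keys[mem$transcript_id], mem$locus_id)
  out <- data.frame(
    locus_id = names(by),
    n_transcripts = lengths(by),
    n_isoforms = vapply(by, function(k) length(unique(k)), integer(1)),
    row.names = NULL
  )
  out[order(-out$n_isoforms, out$locus_id), ]
}
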