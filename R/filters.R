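#' Cascade configuration
#'
#' All thresholds of the candidate-filtering cascade in one list, so a
#' run is reproducible from a single config. Defaults follow the
#' pipeline's published operating point: transcripts shorter than 200 nt
#' spliced or with fewer than 2 exons are dropped; protein-database hits
#' at e-value < 1e-3 disqualify; ORFs longer than 300 nt disqualify;
#' only coding-potential scores <= -1 are retained; domain and
#' ncRNA-family hits below their e-value cutoffs disqualify.
#'
#' @param min_len_nt minimum spliced length, inclusive
#' @param min_exons minimum exon count, inclusive
#' @param max_orf_nt longest-ORF removal threshold (strict >)
#' @param evalue_protein,evalue_domain,evalue_ncrna per-table e-value
#'   cutoffs (strict <)
#' @param cpc_max_score coding-potential retention threshold (inclusive <=)
#' @param missing_score policy for candidates absent from the
#'   coding-potential table: `"drop"` (default, conservative), `"keep"`,
#'   or `"error"`
#' @param orf_both_strands,orf_include_open_ended,orf_mode passed to the
#'   ORF scanner
#' @return named list of class `cascade_config`
#' @export
cascade_config <- function(min_len_nt = 200L, min_exons = 2L,
                           max_orf_nt = 300L,
                           evalue_protein = 1e-3, evalue_domain = 1e-3,
                           evalue_ncrna = 1e-3,
                           cpc_max_score = -1,
                           missing_score = c("drop", "keep", "error"),
                           orf_both_strands = TRUE,
                           orf_include_open_ended = TRUE,
                           orf_mode = "start_stop") {
  missing_score <- match.arg(missing_score)
  structure(list(min_len_nt = min_len_nt, min_exons = min_exons,
                 max_orf_nt = max_orf_nt, evalue_protein = evalue_protein,
                 evalue_domain = evalue_domain, evalue_ncrna = evalue_ncrna,
                 cpc_max_score = cpc_max_score, missing_score = missing_score,
                 orf_both_strands = orf_both_strands,
                 orf_include_open_ended = orf_include_open_ended,
                 orf_mode = orf_mode),
            class = "cascade_config")
}

#' Size/exon-count filter
#'
#' Keeps transcripts with spliced length >= `min_len_nt` AND exon count
#' >= `min_exons` (both inclusive, so a 200-nt two-exon transcript is
#' kept).
#'
#' @param ts a `TranscriptSet`
#' @inheritParams cascade_config
#' @return list with `kept` and `removed` transcript id vectors
#' @export
size_filter <- function(ts, min_len_nt = 200L, min_exons = 2L) {
  tab <- tx_table(ts)
  ok <- tab$spliced_len >= min_len_nt & tab$n_exons >= min_exons
  list(kept = tab$transcript_id[ok], removed = tab$transcript_id[!ok])
}

#' Homology-based removal
#'
#' A candidate is removed iff it has any hit with e-value strictly below
#' `evalue_cutoff` (a hit at exactly the cutoff does not disqualify).
#' Candidates absent from the table are kept. Hit-table rows whose
#' `query_id` matches no candidate are ignored with a warning.
#'
#' @param candidates character vector of candidate ids
#' @param hits a `hit_table`
#' @param kind expected table kind (`protein_db`, `domain` or
#'   `ncrna_family`); mismatch is an error
#' @param evalue_cutoff strict upper bound for a disqualifying hit
#' @return list with `kept` and `removed`
#' @export
homology_filter <- function(candidates, hits, kind, evalue_cutoff = 1e-3) {
  kind <- match.arg(kind, c("protein_db", "domain", "ncrna_family"))
  if (!inherits(hits, "hit_table")) stop("'hits' must be a hit_table")
  if (attr(hits, "kind") != kind) {
    stop("hit table of kind '", attr(hits, "kind"), "' passed where '",
         kind, "' expected")
  }
  orphan <- setdiff(unique(hits$query_id), candidates)
  if (length(orphan)) {
    warning(length(orphan), " hit-table query id(s) match no candidate ",
            "and were ignored (e.g. ", orphan[1L], ")")
  }
  sig <- hits$query_id[!is.na(hits$evalue) & hits$evalue < evalue_cutoff]
  removed <- candidates %in% sig
  list(kept = candidates[!removed], removed = candidates[removed])
}

#' Coding-potential score filter
#'
#' Retains candidates whose score is <= `max_score` (inclusive: a score
#' of exactly -1 is kept under the default). The score is read from the
#' `score` column of a `coding_potential` hit table (one row per
#' transcript; duplicates take the maximum, the conservative choice).
#'
#' @param candidates character vector of candidate ids
#' @param scores `hit_table` of kind `coding_potential`
#' @param max_score inclusive retention threshold
#' @param missing policy for candidates without a score: `"drop"`
#'   (removed, with a warning), `"keep"`, or `"error"`
#' @return list with `kept`, `removed` and `missing` (ids without scores)
#' @export
coding_potential_filter <- function(candidates, scores, max_score = -1,
                                    missing = c("drop", "keep", "error")) {
  missing <- match.arg(missing)
  if (!inherits(scores, "hit_table") || attr(scores, "kind") != "coding_potential") {
    stop("'scores' must be a hit_table of kind 'coding_potential'")
  }
  sc <- tapply(scores$score, scores$query_id, max)
  val <- sc[candidates]
  no_score <- is.na(val)
  if (any(no_score)) {
    if (missing == "error") {
      stop("candidates without coding-potential score: ",
           paste(candidates[no_score], collapse = ", "))
    }
    if (missing == "drop") {
      warning(sum(no_score), " candidate(s) without coding-potential score ",
              "dropped (missing-score policy)")
    }
  }
  keep <- ifelse(no_score, missing == "keep", val <= max_score)
  list(kept = candidates[keep], removed = candidates[!keep],
       missing = candidates[no_score])
}

#' Run the full lncRNA candidate cascade
#'
#' Applies, in order: size/exon filter; protein-database homology
#' removal; ORF-length removal; coding-potential score retention;
#' protein-domain removal; ncRNA-family removal. Each step sees only the
#' survivors of the previous one, and each removed transcript is
#' attributed to exactly the first step that rejects it, so the final
#' kept set equals the intersection of the per-step kept sets.
#'
#' @param ts candidate `TranscriptSet`
#' @param seqs named character vector of candidate sequences; every
#'   transcript in `ts` must have one (orphans on either side are an
#'   error)
#' @param hits named list with optional elements `protein_db`, `domain`,
#'   `ncrna_family`, `coding_potential`, each a `hit_table`. A missing
#'   protein/domain/family table removes nothing; a missing
#'   coding-potential table skips that step.
#' @param config a [cascade_config()]
#' @return object of class `filter_report`: list with `steps`
#'   (data.frame `step`, `n_in`, `n_kept`, `n_removed`), `removed`
#'   (named list of removed-id vectors per step), `kept` (final lncRNA
#'   candidate ids) and `orf_report`
#' @export
run_cascade <- function(ts, seqs, hits = list(), config = cascade_config()) {
  ids <- tx_ids(ts)
  miss_seq <- setdiff(ids, names(seqs))
  if (length(miss_seq)) {
    stop("transcript(s) without a sequence: ", paste(miss_seq, collapse = ", "))
  }
  extra_seq <- setdiff(names(seqs), ids)
  if (length(extra_seq)) {
    stop("sequence id(s) not in the transcript set: ",
         paste(extra_seq, collapse = ", "))
  }

  steps <- list(); removed <- list(); orf_rep <- NULL
  cur <- ids
  note <- function(name, res) {
    steps[[name]] <<- data.frame(step = name, n_in = length(cur),
                                 n_kept = length(res$kept),
                                 n_removed = length(res$removed))
    removed[[name]] <<- res$removed
    cur <<- res$kept
  }

  note("size", size_filter(ts, config$min_len_nt, config$min_exons))

  pdb <- if (is.null(hits$protein_db)) empty_hit_table("protein_db") else hits$protein_db
  note("protein_db", suppressWarnings(
    homology_filter(cur, pdb, "protein_db", config$evalue_protein)))

  orf_res <- orf_filter(seqs[cur], config$max_orf_nt, config$orf_both_strands,
                        config$orf_include_open_ended, config$orf_mode)
  orf_rep <- orf_res$report
  note("orf", orf_res)

  if (!is.null(hits$coding_potential)) {
    note("coding_potential", suppressWarnings(
      coding_potential_filter(cur, hits$coding_potential,
                              config$cpc_max_score, config$missing_score)))
  }

  dom <- if (is.null(hits$domain)) empty_hit_table("domain") else hits$domain
  note("domain", suppressWarnings(
    homology_filter(cur, dom, "domain", config$evalue_domain)))

  fam <- if (is.null(hits$ncrna_family)) empty_hit_table("ncrna_family") else hits$ncrna_family
  note("ncrna_family", suppressWarnings(
    homology_filter(cur, fam, "ncrna_family", config$evalue_ncrna)))

  structure(list(steps = do.call(rbind, c(steps, list(make.row.names = FALSE))),
                 removed = removed, kept = cur, orf_report = orf_rep,
                 config = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("lncRNA candidate cascade:\n")
  print(x$steps, row.names = FALSE)
  cat(sprintf("final candidates: %d\n", length(x$kept)))
  invisible(x)
}

#' Map each removed transcript to the step that removed it
#'
#' @param report a `filter_report`
#' @return data.frame `transcript_id`, `removed_at` (step name or
#'   `"survivor"`)
#' @export
removal_attribution <- function(report) {
  out <- data.frame(transcript_id = report$kept, removed_at = "survivor")
  for (s in names(report$removed)) {
    ids <- report$removed[[s]]
    if (length(ids)) {
      out <- rbind(out, data.frame(transcript_id = ids, removed_at = s))
    }
  }
  out[order(out$transcript_id), ]
}
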