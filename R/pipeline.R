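#' Pipeline configuration
#'
#' All knobs for an end-to-end run: the cascade thresholds plus the
#' expression and association parameters. Unknown keys are rejected so a
#' typo in a config file cannot silently fall back to a default.
#'
#' @param cascade a [cascade_config()]
#' @param high_cut,low_cut,fold_cut,combine specificity parameters
#'   (see [call_specific()])
#' @param p_cut,q_cut,pseudocount differential parameters
#'   (see [call_differential()])
#' @param strong_cut co-expression strength threshold
#' @param window_bp,max_report_bp neighbour parameters
#'   (see [find_neighbors()])
#' @param present_above per-sample presence threshold for the
#'   classification table
#' @param run_expression,run_association step toggles
#' @return named list of class `pipeline_config`
#' @export
pipeline_config <- function(cascade = cascade_config(),
                            high_cut = 3, low_cut = 1, fold_cut = 10,
                            combine = "AND",
                            p_cut = 0.05, q_cut = 0.05, pseudocount = 0.1,
                            strong_cut = 0.8,
                            window_bp = 10000L, max_report_bp = 50000L,
                            present_above = 0,
                            run_expression = TRUE, run_association = TRUE) {
  structure(list(cascade = cascade, high_cut = high_cut, low_cut = low_cut,
                 fold_cut = fold_cut, combine = combine, p_cut = p_cut,
                 q_cut = q_cut, pseudocount = pseudocount,
                 strong_cut = strong_cut, window_bp = window_bp,
                 max_report_bp = max_report_bp, present_above = present_above,
                 run_expression = run_expression,
                 run_association = run_association),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys must be arguments of [pipeline_config()]; keys under
#' `cascade` must be arguments of [cascade_config()]. Unknown keys are
#' an error.
#'
#' @param path YAML file
#' @return `pipeline_config`
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  casc_args <- raw$cascade
  raw$cascade <- NULL
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(casc_args)) {
    unknown <- setdiff(names(casc_args), names(formals(cascade_config)))
    if (length(unknown)) stop("unknown cascade config key(s): ",
                              paste(unknown, collapse = ", "))
    raw$cascade <- do.call(cascade_config, casc_args)
  }
  do.call(pipeline_config, raw)
}

#' Run the full lncRNA discovery pipeline
#'
#' Orchestrates filter cascade, known-isoform exclusion, positional
#' classification, locus clustering, structural summary, expression
#' calls and neighbour association as one reproducible run. Each
#' stage's output feeds the next: only cascade survivors are
#' classified, only classified lncRNAs enter the expression and
#' association stages.
#'
#' @param candidates candidate `TranscriptSet`
#' @param sequences named character vector of candidate sequences
#' @param reference an `AnnotationIndex`
#' @param hits named list of `hit_table`s (see [run_cascade()])
#' @param expr optional FPKM matrix covering candidates (and reference
#'   genes, for link annotation)
#' @param groups optional named list of two sample-name vectors for the
#'   differential stage
#' @param config a [pipeline_config()]
#' @param out_dir when given, all result tables are written there as
#'   TSV/GTF/FASTA plus a `manifest.json` with the echoed config,
#'   package version, input checksums and per-stage counts
#' @return list with `filter_report`, `known`, `classes`, `loci`,
#'   `class_table`, `structure`, `specific`, `differential`,
#'   `neighbors`, `links`, `manifest`
#' @export
run_pipeline <- function(candidates, sequences, reference, hits = list(),
                         expr = NULL, groups = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list(candidates_in = length(candidates))

  report <- run_cascade(candidates, sequences, hits, config$cascade)
  counts$cascade_survivors <- length(report$kept)

  surv <- tx_subset(candidates, report$kept)
  known <- flag_known_transcripts(surv, reference)
  lnc <- if (any(known)) tx_subset(surv, names(known)[!known]) else surv
  counts$known_excluded <- sum(known)
  counts$lncrna <- length(lnc)

  classes <- classify_transcripts(lnc, reference)
  loci <- cluster_loci(lnc)
  counts$classified <- nrow(classes)
  counts$loci <- nrow(loci$loci)
  class_tab <- classification_table(classes,
                                    expr = if (!is.null(expr)) expr else NULL,
                                    present_above = config$present_above)

  structure_sum <- summarize_structure(lnc, coding = reference$tx, loci = loci)

  specific <- NULL; differential <- NULL
  if (config$run_expression && !is.null(expr)) {
    lnc_expr <- expr[intersect(rownames(expr), tx_ids(lnc)), , drop = FALSE]
    specific <- call_specific(lnc_expr, config$high_cut, config$low_cut,
                              config$fold_cut, config$combine)
    counts$specific_called <- sum(specific$specific)
    if (!is.null(groups)) {
      differential <- call_differential(lnc_expr, groups[[1L]], groups[[2L]],
                                        config$p_cut, config$q_cut,
                                        config$pseudocount)
      counts$differential_called <- sum(differential$significant, na.rm = TRUE)
    }
  }

  neighbors <- NULL; links <- NULL
  if (config$run_association) {
    neighbors <- find_neighbors(lnc, reference, config$window_bp,
                                config$max_report_bp)
    counts$neighbor_links <- nrow(neighbors)
    counts$within_window <- sum(neighbors$within_window)
    links <- if (!is.null(expr)) {
      suppressWarnings(annotate_links(neighbors, expr, config$strong_cut))
    } else neighbors
  }

  manifest <- list(
    package = "lncscout",
    version = as.character(utils::packageVersion("lncscout")),
    config = unclass_config(config),
    counts = counts
  )

  out <- list(filter_report = report, known = known, classes = classes,
              loci = loci, class_table = class_tab,
              structure = structure_sum, specific = specific,
              differential = differential, neighbors = neighbors,
              links = links, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, lnc, sequences, out_dir)
  out
}

# config lists as plain nestable lists for JSON echo
unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$cascade <- unclass(cfg$cascade)
  cfg
}

write_pipeline_outputs <- function(res, lnc, sequences, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$filter_report$steps, "filter_steps.tsv")
  wt(removal_attribution(res$filter_report), "removal_attribution.tsv")
  write_gtf(lnc, file.path(out_dir, "lncrna.gtf"))
  write_fasta(sequences[tx_ids(lnc)], file.path(out_dir, "lncrna.fa"))
  wt(res$classes, "classes.tsv")
  wt(res$loci$members, "locus_members.tsv")
  wt(res$loci$loci, "loci.tsv")
  ct <- data.frame(category = rownames(res$class_table), res$class_table,
                   check.names = FALSE)
  wt(ct, "classification_table.tsv")
  wt(res$structure$exon_count_hist, "exon_count_hist.tsv")
  wt(res$structure$length_summary, "length_summary.tsv")
  wt(res$structure$scaffold_hist, "scaffold_locus_hist.tsv")
  if (!is.null(res$specific)) wt(res$specific, "specific_calls.tsv")
  if (!is.null(res$differential)) wt(res$differential, "differential_calls.tsv")
  if (!is.null(res$links)) wt(res$links, "neighbor_links.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export transcripts as BED12
#'
#' One BED12 line per transcript with exon blocks; useful for genome
#' browsers. Coordinates follow BED's 0-based half-open convention on
#' output.
#'
#' @param ts a `TranscriptSet`
#' @param path output file
#' @param category optional named vector (by transcript id) written into
#'   the BED name field as `id|category`
#' @return `path`, invisibly
#' @export
write_bed12 <- function(ts, path, category = NULL) {
  tab <- tx_table(ts)
  ex <- tx_exons(ts)
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    id <- tab$transcript_id[i]
    sel <- which(tid == id)
    sizes <- en[sel] - st[sel] + 1L
    starts0 <- st[sel] - tab$start[i]
    name <- if (!is.null(category) && id %in% names(category)) {
      paste0(id, "|", category[[id]])
    } else id
    paste(tab$seqnames[i], tab$start[i] - 1L, tab$end[i], name, 0,
          if (tab$strand[i] %in% c("+", "-")) tab$strand[i] else ".",
          tab$start[i] - 1L, tab$end[i], "0", length(sel),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
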