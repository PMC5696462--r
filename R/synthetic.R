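#' Seeded synthetic genome with multi-exon coding genes
#'
#' Emulates a fragmented draft genome: several scaffolds of random
#' sequence carrying non-overlapping multi-exon protein-coding genes on
#' both strands, separated by wide intergenic gaps (>= 25 kb by default,
#' at least twice the neighbour-calling window) so that intergenic
#' placements of planted candidates are unambiguous. Deterministic
#' given `seed`.
#'
#' @param n_scaffolds number of scaffolds
#' @param scaffold_len length of each scaffold, bp
#' @param n_genes total genes, distributed over scaffolds in layout order
#' @param seed RNG seed (the function sets the seed)
#' @param intergenic_bp minimum gap between consecutive gene spans
#' @param exon_range,intron_range,n_exon_range sampling ranges for gene
#'   structure (2-8 exons of 150-400 bp with 500-3,000 bp introns by
#'   default)
#' @return list with `genome` (named character vector of scaffold
#'   sequences), `annotation` (an `AnnotationIndex`, one transcript per
#'   gene, biotype `protein_coding`) and `scaffold_len`
#' @export
generate_genome <- function(n_scaffolds = 5L, scaffold_len = 400000L,
                            n_genes = 40L, seed = 1L,
                            intergenic_bp = 25000L,
                            exon_range = c(150L, 400L),
                            intron_range = c(500L, 3000L),
                            n_exon_range = c(2L, 8L)) {
  set.seed(seed)
  scaf_names <- sprintf("scaffold_%d", seq_len(n_scaffolds))
  genome <- stats::setNames(vapply(scaf_names, function(s) {
    paste(sample(c("A", "C", "G", "T"), scaffold_len, replace = TRUE),
          collapse = "")
  }, character(1)), scaf_names)

  rows <- list()
  gi <- 0L
  for (sc in scaf_names) {
    cursor <- sample(3000:8000, 1L)
    repeat {
      if (gi >= n_genes) break
      ne <- sample(n_exon_range[1L]:n_exon_range[2L], 1L)
      ew <- sample(exon_range[1L]:exon_range[2L], ne, replace = TRUE)
      iw <- if (ne > 1L) sample(intron_range[1L]:intron_range[2L], ne - 1L,
                                replace = TRUE) else integer(0)
      span <- sum(ew) + sum(iw)
      if (cursor + span > scaffold_len - 3000L) break
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      starts <- cursor + cumsum(c(0L, ew[-ne] + iw))
      rows[[gi]] <- data.frame(
        seqnames = sc, start = starts, end = starts + ew - 1L,
        strand = strand,
        transcript_id = sprintf("ref_g%03d.t1", gi),
        gene_id = sprintf("ref_g%03d", gi))
      cursor <- cursor + span + intergenic_bp + sample(0:5000, 1L)
    }
    if (gi >= n_genes) break
  }
  if (gi < n_genes) {
    stop("could not place ", n_genes, " genes at the requested density; ",
         "placed ", gi)
  }
  ex <- do.call(rbind, rows)
  if (is.null(ex)) {
    ex <- data.frame(seqnames = character(), start = integer(),
                     end = integer(), strand = character(),
                     transcript_id = character(), gene_id = character())
  }
  gr <- GenomicRanges::GRanges(ex$seqnames,
                               IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  ann <- annotation_index(transcript_set(gr), biotype = "protein_coding")
  list(genome = genome, annotation = ann, scaffold_len = scaffold_len)
}

#' Planted-candidate design
#'
#' Counts per planted positional class (all cascade survivors) and per
#' planted removal fate. Defaults give >= 10 exemplars per positional
#' category and a ~460-candidate fixture.
#'
#' @param intergenic,intronic_sense,intronic_antisense,exonic_sense,exonic_antisense,junction,unclassified
#'   survivor counts per positional category
#' @param size_fail transcripts failing the size/exon filter (half
#'   single-exon, half spliced length < 200 nt)
#' @param nr_hit transcripts removed by protein-database homology
#' @param long_orf transcripts carrying an embedded 450-nt ORF, removed
#'   by the ORF-length step
#' @param cpc_fail transcripts with coding-potential score > -1
#' @param domain_hit transcripts removed by a protein-domain hit
#' @param ncrna_decoy housekeeping-ncRNA decoys removed by the
#'   ncRNA-family step
#' @return named list of counts
#' @export
candidate_design <- function(intergenic = 40L, intronic_sense = 40L,
                             intronic_antisense = 40L, exonic_sense = 40L,
                             exonic_antisense = 40L, junction = 40L,
                             unclassified = 40L,
                             size_fail = 30L, nr_hit = 30L, long_orf = 30L,
                             cpc_fail = 30L, domain_hit = 30L,
                             ncrna_decoy = 30L) {
  list(intergenic = intergenic, intronic_sense = intronic_sense,
       intronic_antisense = intronic_antisense, exonic_sense = exonic_sense,
       exonic_antisense = exonic_antisense, junction = junction,
       unclassified = unclassified, size_fail = size_fail, nr_hit = nr_hit,
       long_orf = long_orf, cpc_fail = cpc_fail, domain_hit = domain_hit,
       ncrna_decoy = ncrna_decoy)
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# rejection-sample a sequence whose longest six-frame ORF is <= max_orf
.make_noncoding <- function(len, max_orf = 210L, tries = 300L) {
  for (i in seq_len(tries)) {
    s <- .random_dna(len)
    lo <- find_orfs(s, both_strands = TRUE, include_open_ended = TRUE)
    if (nrow(lo) == 0L || lo$length_nt[1L] <= max_orf) return(s)
  }
  stop("rejection sampling failed for a noncoding sequence of length ", len,
       "; try shorter sequences")
}

# embed an ATG ... stop ORF of orf_nt nucleotides at a random frame-1
# position of a random background
.make_coding <- function(len, orf_nt = 450L) {
  stopifnot(len >= orf_nt, orf_nt %% 3L == 0L)
  s <- .random_dna(len)
  codons <- c("GCA", "GCC", "GAA", "GGT", "TTA", "CTG", "AAA", "CCC", "AGT",
              "ACA", "GAT", "TGC", "CAT", "ATC", "TTC", "GTA")
  n_mid <- orf_nt / 3L - 2L
  orf <- paste0("ATG", paste(sample(codons, n_mid, replace = TRUE),
                             collapse = ""), "TAA")
  pos <- sample.int(len - orf_nt + 1L, 1L)
  paste0(substring(s, 1L, pos - 1L), orf, substring(s, pos + orf_nt, len))
}

#' Planted lncRNA candidates with known positional class and ORF content
#'
#' Constructs candidate transcript models with unambiguous geometry for
#' each positional category (e.g. intronic candidates fully inside a
#' single reference intron with >= 50 bp margins; junction candidates
#' copying exactly one reference intron of a >= 3-exon gene), plus
#' transcripts planted to fail each cascade step. Candidate sequences
#' are generated to match the planted coding status: "coding" sequences
#' embed a 450-nt ORF, "noncoding" sequences are rejection-sampled until
#' their longest six-frame ORF is <= 210 nt (measured with the package's
#' own scanner).
#'
#' @param genome output of [generate_genome()]
#' @param design a [candidate_design()]
#' @param seed RNG seed (the function sets the seed)
#' @return list with `candidates` (`TranscriptSet`), `sequences` (named
#'   character vector) and `truth` (data.frame `transcript_id`,
#'   `planted_class`, `coding_status`, `planted_removal`
#'   (step name or `"survivor"`), `longest_orf_nt`)
#' @export
generate_candidates <- function(genome, design = candidate_design(), seed = 1L) {
  set.seed(seed)
  ann <- genome$annotation
  genes <- ann$genes
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gst <- GenomicRanges::start(genes); gen_ <- GenomicRanges::end(genes)
  gstr <- as.character(GenomicRanges::strand(genes))

  # intergenic gaps wide enough for safe placement
  gaps <- list()
  for (sc in names(genome$genome)) {
    on <- which(gchr == sc)
    bounds <- sort(c(1L, gst[on] - 1L, gen_[on] + 1L, genome$scaffold_len))
    lo <- c(1L, gen_[on][order(gst[on])] + 1L)
    hi <- c(gst[on][order(gst[on])] - 1L, genome$scaffold_len)
    for (k in seq_along(lo)) {
      if (hi[k] - lo[k] + 1L >= 14000L) {
        gaps[[length(gaps) + 1L]] <- list(seqnames = sc, start = lo[k], end = hi[k])
      }
    }
  }
  if (!length(gaps)) stop("no intergenic gap wide enough for placement")

  introns <- ann$introns
  iw <- GenomicRanges::width(introns)
  big_introns <- introns[iw >= 420L]
  if (length(big_introns) == 0L) stop("no reference intron >= 420 bp")
  ref_ex <- ann$exons
  wide_ex <- ref_ex[GenomicRanges::width(ref_ex) >= 150L]
  multi_tx <- ann$tx$tx$transcript_id[ann$tx$tx$n_exons >= 3L]
  if (length(multi_tx) == 0L) stop("no reference transcript with >= 3 exons")

  ex_rows <- list()
  truth <- list()
  cnt <- 0L
  emit <- function(exdf, class, status, removal) {
    cnt <<- cnt + 1L
    id <- sprintf("cand_%04d", cnt)
    exdf$transcript_id <- id
    exdf$gene_id <- sprintf("CLOC_%04d", cnt)
    ex_rows[[cnt]] <<- exdf
    truth[[cnt]] <<- data.frame(transcript_id = id, planted_class = class,
                                coding_status = status,
                                planted_removal = removal)
    id
  }

  place_in_gap <- function(widths, intron_w, strand = sample(c("+", "-"), 1L)) {
    g <- gaps[[sample.int(length(gaps), 1L)]]
    total <- sum(widths) + sum(intron_w)
    lo <- g$start + 3000L
    hi <- g$end - 3000L - total
    st0 <- sample(lo:hi, 1L)
    starts <- st0 + cumsum(c(0L, widths[-length(widths)] + intron_w))
    data.frame(seqnames = g$seqnames, start = starts,
               end = starts + widths - 1L, strand = strand)
  }

  gap_candidate <- function() {
    ne <- sample(2:3, 1L)
    widths <- sample(130:220, ne, replace = TRUE)
    place_in_gap(widths, sample(80:400, ne - 1L, replace = TRUE))
  }

  for (i in seq_len(design$intergenic)) {
    emit(gap_candidate(), "INTERGENIC", "noncoding", "survivor")
  }

  intronic <- function(opposite) {
    I <- big_introns[sample.int(length(big_introns), 1L)]
    istr <- as.character(GenomicRanges::strand(I))
    widths <- c(125L, 125L)
    iwc <- 60L
    lo <- GenomicRanges::start(I) + 50L
    hi <- GenomicRanges::end(I) - 50L - (sum(widths) + iwc) + 1L
    st0 <- if (hi > lo) sample(lo:hi, 1L) else lo
    starts <- st0 + cumsum(c(0L, widths[1L] + iwc))
    data.frame(seqnames = as.character(GenomicRanges::seqnames(I)),
               start = starts, end = starts + widths - 1L,
               strand = if (opposite) setdiff(c("+", "-"), istr) else istr)
  }
  for (i in seq_len(design$intronic_sense)) {
    emit(intronic(FALSE), "INTRONIC_SENSE", "noncoding", "survivor")
  }
  for (i in seq_len(design$intronic_antisense)) {
    emit(intronic(TRUE), "INTRONIC_ANTISENSE", "noncoding", "survivor")
  }

  exonic <- function(opposite) {
    E <- wide_ex[sample.int(length(wide_ex), 1L)]
    es <- GenomicRanges::start(E)
    estr <- as.character(GenomicRanges::strand(E))
    starts <- c(es - 80L, es + 221L)
    ends <- c(es + 70L, es + 350L)
    data.frame(seqnames = as.character(GenomicRanges::seqnames(E)),
               start = starts, end = ends,
               strand = if (opposite) setdiff(c("+", "-"), estr) else estr)
  }
  for (i in seq_len(design$exonic_sense)) {
    emit(exonic(FALSE), "EXONIC_SENSE", "noncoding", "survivor")
  }
  for (i in seq_len(design$exonic_antisense)) {
    emit(exonic(TRUE), "EXONIC_ANTISENSE", "noncoding", "survivor")
  }

  junction <- function() {
    tid <- sample(multi_tx, 1L)
    tin <- introns[as.character(S4Vectors::mcols(introns)$transcript_id) == tid]
    I <- tin[sample.int(length(tin), 1L)]
    data.frame(seqnames = as.character(GenomicRanges::seqnames(I)),
               start = c(GenomicRanges::start(I) - 120L,
                         GenomicRanges::end(I) + 1L),
               end = c(GenomicRanges::start(I) - 1L,
                       GenomicRanges::end(I) + 130L),
               strand = as.character(GenomicRanges::strand(I)))
  }
  for (i in seq_len(design$junction)) {
    emit(junction(), "JUNCTION_SHARE", "noncoding", "survivor")
  }

  # one exon inside a gene's last intron, one beyond the gene end:
  # gene-span overlap without exon overlap -> unclassified
  unclassified <- function() {
    gi <- sample.int(length(genes), 1L)
    g <- genes[gi]
    gid <- as.character(S4Vectors::mcols(g)$gene_id)
    gin <- introns[as.character(S4Vectors::mcols(introns)$gene_id) == gid]
    gin <- gin[GenomicRanges::width(gin) >= 230L]
    if (length(gin) == 0L) return(NULL)
    I <- gin[which.max(GenomicRanges::start(gin))]
    e1s <- GenomicRanges::start(I) + 50L
    e2s <- GenomicRanges::end(g) + 200L
    data.frame(seqnames = as.character(GenomicRanges::seqnames(g)),
               start = c(e1s, e2s), end = c(e1s + 124L, e2s + 129L),
               strand = as.character(GenomicRanges::strand(g)))
  }
  i <- 0L
  while (i < design$unclassified) {
    u <- unclassified()
    if (is.null(u)) next
    emit(u, "UNCLASSIFIED", "noncoding", "survivor")
    i <- i + 1L
  }

  # planted cascade failures, all placed intergenically
  for (i in seq_len(design$size_fail)) {
    exdf <- if (i %% 2L == 0L) {
      place_in_gap(1000L, integer(0))           # single exon
    } else {
      place_in_gap(c(70L, 70L), 100L)           # spliced length 140 < 200
    }
    emit(exdf, "INTERGENIC", "noncoding", "size")
  }
  for (i in seq_len(design$nr_hit)) {
    emit(place_in_gap(c(150L, 150L), 200L), "INTERGENIC", "noncoding",
         "protein_db")
  }
  for (i in seq_len(design$long_orf)) {
    emit(place_in_gap(c(260L, 260L), 200L), "INTERGENIC", "coding", "orf")
  }
  for (i in seq_len(design$cpc_fail)) {
    emit(place_in_gap(c(150L, 150L), 200L), "INTERGENIC", "noncoding",
         "coding_potential")
  }
  for (i in seq_len(design$domain_hit)) {
    emit(place_in_gap(c(150L, 150L), 200L), "INTERGENIC", "noncoding", "domain")
  }
  for (i in seq_len(design$ncrna_decoy)) {
    emit(place_in_gap(c(150L, 150L), 200L), "INTERGENIC", "noncoding",
         "ncrna_family")
  }

  ex <- do.call(rbind, ex_rows)
  gr <- GenomicRanges::GRanges(ex$seqnames, IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  ts <- transcript_set(gr)
  truth <- do.call(rbind, truth)

  # sequences matched to spliced lengths and planted coding status
  tab <- tx_table(ts)
  lens <- stats::setNames(tab$spliced_len, tab$transcript_id)
  seqs <- vapply(truth$transcript_id, function(id) {
    L <- as.integer(lens[[id]])
    if (truth$coding_status[truth$transcript_id == id] == "coding") {
      .make_coding(L, 450L)
    } else {
      .make_noncoding(L)
    }
  }, character(1))
  truth$longest_orf_nt <- longest_orfs(seqs)$longest_orf_nt[
    match(truth$transcript_id, names(seqs))]

  list(candidates = ts, sequences = seqs, truth = truth)
}

#' Homology and coding-potential tables for planted candidates
#'
#' Each planted fate receives the table entries that trigger it:
#' protein-database hits for `protein_db` plants, domain hits for
#' `domain` plants, ncRNA-family hits for the housekeeping decoys, and
#' a coding-potential score for every candidate (<= -1 for planted
#' noncoding survivors, > -1 for `coding_potential` plants and for
#' transcripts already removed upstream).
#'
#' @param truth truth data.frame from [generate_candidates()]
#' @param seed RNG seed (the function sets the seed)
#' @return named list of `hit_table`s: `protein_db`, `domain`,
#'   `ncrna_family`, `coding_potential`
#' @export
generate_hit_tables <- function(truth, seed = 1L) {
  set.seed(seed)
  ids_of <- function(step) truth$transcript_id[truth$planted_removal == step]

  mk_hits <- function(ids, subjects, kind, emin = 1e-12, emax = 1e-5) {
    if (!length(ids)) return(empty_hit_table(kind))
    hit_table(data.frame(
      query_id = ids,
      subject = sample(subjects, length(ids), replace = TRUE),
      evalue = 10^stats::runif(length(ids), log10(emin), log10(emax)),
      score = round(stats::runif(length(ids), 50, 400), 1)), kind)
  }

  pdb <- mk_hits(ids_of("protein_db"),
                 sprintf("NP_%06d.1", 1:500), "protein_db")
  dom <- mk_hits(ids_of("domain"),
                 c("PF00001", "PF00067", "PF07690", "PF00069"), "domain")
  fam <- mk_hits(ids_of("ncrna_family"),
                 c("5S_rRNA", "U6", "SNORD14", "tRNA", "U2"), "ncrna_family")

  removed_early <- truth$planted_removal %in%
    c("size", "protein_db", "orf", "coding_potential")
  coding_like <- truth$coding_status == "coding" |
    truth$planted_removal == "coding_potential" |
    (removed_early & truth$planted_removal %in% c("size", "protein_db"))
  score <- ifelse(coding_like,
                  round(stats::runif(nrow(truth), -0.9, 3), 3),
                  round(stats::runif(nrow(truth), -3, -1.05), 3))
  cpc <- if (nrow(truth) == 0L) empty_hit_table("coding_potential") else
    hit_table(data.frame(query_id = truth$transcript_id,
                         subject = NA_character_, evalue = 0,
                         score = score), "coding_potential")
  list(protein_db = pdb, domain = dom, ncrna_family = fam,
       coding_potential = cpc)
}

#' Expression-design helper
#'
#' @param specific data.frame `transcript_id`, `focal_sample`
#' @param differential list with `groups` (named list of two character
#'   vectors of sample names), `plants` (data.frame `transcript_id`,
#'   `log2fc`) and optional `noise_sd` (within-group SD in log2 units,
#'   default 0.25), or NULL
#' @param coexpr data.frame `id_x`, `id_y`, `target_r`, or NULL
#' @return list passed to [generate_expression()]
#' @export
expression_design <- function(specific = NULL, differential = NULL,
                              coexpr = NULL) {
  list(specific = specific, differential = differential, coexpr = coexpr)
}

#' Synthetic FPKM matrix with planted expression truths
#'
#' Baseline abundance is log-normal with median ~5 FPKM and moderate
#' per-sample noise. Planted specific transcripts get a focal FPKM in
#' [10, 50] and [0.05, 0.5] everywhere else, satisfying both the
#' high/low and the 10-fold specificity rule. Planted co-expressed pairs
#' share a fixed standardised latent profile across samples (a
#' deterministic tissue-like gradient) with independent noise, with
#' loadings sqrt(r) so the pair correlation equals `target_r` in
#' expectation. Planted differential transcripts shift one group's mean
#' by `log2fc` on the log2 scale (within-group noise SD `noise_sd`,
#' default 0.25 log2 units).
#'
#' @param ids transcript ids to emit rows for
#' @param n_samples number of samples (>= 4 when `coexpr` plants exist)
#' @param design an [expression_design()]
#' @param seed RNG seed (the function sets the seed)
#' @param sample_names defaults to S1..Sn, or the union of the
#'   differential group names when given
#' @param baseline_meanlog,baseline_sdlog,noise_sdlog baseline model
#'   parameters (natural-log scale)
#' @return list with `matrix` (FPKM), `truth` (data.frame
#'   `transcript_id`, `role`, `focal_sample`, `log2fc`, `partner`,
#'   `target_r`) and `groups`
#' @export
generate_expression <- function(ids, n_samples = 4L,
                                design = expression_design(), seed = 1L,
                                sample_names = NULL,
                                baseline_meanlog = log(5),
                                baseline_sdlog = 0.8,
                                noise_sdlog = 0.25) {
  set.seed(seed)
  if (is.null(sample_names)) {
    sample_names <- if (!is.null(design$differential)) {
      unlist(design$differential$groups, use.names = FALSE)
    } else {
      sprintf("S%d", seq_len(n_samples))
    }
  }
  n_samples <- length(sample_names)
  if (!is.null(design$coexpr) && nrow(design$coexpr) > 0L && n_samples < 4L) {
    stop("co-expression designs need >= 4 samples")
  }
  if (!is.null(design$coexpr) &&
      any(abs(design$coexpr$target_r) >= 1)) {
    stop("target_r must lie strictly within (-1, 1)")
  }

  mu <- stats::rlnorm(length(ids), baseline_meanlog, baseline_sdlog)
  noise <- matrix(stats::rnorm(length(ids) * n_samples, 0, noise_sdlog),
                  nrow = length(ids))
  mat <- mu * exp(noise)
  dimnames(mat) <- list(ids, sample_names)

  truth <- data.frame(transcript_id = ids, role = "baseline",
                      focal_sample = NA_character_, log2fc = NA_real_,
                      partner = NA_character_, target_r = NA_real_)

  if (!is.null(design$specific) && nrow(design$specific) > 0L) {
    for (k in seq_len(nrow(design$specific))) {
      id <- design$specific$transcript_id[k]
      focal <- design$specific$focal_sample[k]
      mat[id, ] <- stats::runif(n_samples, 0.05, 0.5)
      mat[id, focal] <- stats::runif(1L, 10, 50)
      truth[truth$transcript_id == id,
            c("role", "focal_sample")] <- list("specific", focal)
    }
  }

  if (!is.null(design$differential)) {
    ga <- design$differential$groups[[1L]]
    gb <- design$differential$groups[[2L]]
    pl <- design$differential$plants
    nsd <- design$differential$noise_sd
    if (is.null(nsd)) nsd <- 0.25
    for (k in seq_len(nrow(pl))) {
      id <- pl$transcript_id[k]
      base <- stats::rlnorm(1L, log(20), 0.3)
      mat[id, ga] <- base * 2^stats::rnorm(length(ga), 0, nsd)
      mat[id, gb] <- base * 2^(pl$log2fc[k] + stats::rnorm(length(gb), 0, nsd))
      truth[truth$transcript_id == id,
            c("role", "log2fc")] <- list("differential", pl$log2fc[k])
    }
  }

  if (!is.null(design$coexpr) && nrow(design$coexpr) > 0L) {
    for (k in seq_len(nrow(design$coexpr))) {
      idx_ <- as.character(design$coexpr$id_x[k])
      idy <- as.character(design$coexpr$id_y[k])
      r <- design$coexpr$target_r[k]
      f <- as.numeric(scale(stats::rnorm(n_samples)))  # standardised profile
      load <- sqrt(abs(r))
      zx <- load * f + sqrt(1 - abs(r)) * stats::rnorm(n_samples)
      zy <- sign(r) * load * f + sqrt(1 - abs(r)) * stats::rnorm(n_samples)
      mux <- stats::rlnorm(1L, log(20), 0.3)
      muy <- stats::rlnorm(1L, log(20), 0.3)
      mat[idx_, ] <- pmax(0.01, mux + 0.3 * mux * zx)
      mat[idy, ] <- pmax(0.01, muy + 0.3 * muy * zy)
      truth[truth$transcript_id == idx_,
            c("role", "partner", "target_r")] <- list("coexpr", idy, r)
      truth[truth$transcript_id == idy,
            c("role", "partner", "target_r")] <- list("coexpr", idx_, r)
    }
  }

  groups <- if (!is.null(design$differential)) design$differential$groups else NULL
  list(matrix = mat, truth = truth, groups = groups)
}

#' Default end-to-end fixture
#'
#' Builds the full synthetic study in one call: a 5-scaffold genome with
#' 40 coding genes, ~460 planted candidates covering every positional
#' category and every cascade-removal fate, the four homology /
#' coding-potential tables, and a 4-sample FPKM matrix with 20 planted
#' sample-specific lncRNAs among the survivors (focal samples assigned
#' round-robin) and null baselines elsewhere. Reference gene ids get
#' expression rows too so neighbour links can be annotated with
#' co-expression.
#'
#' @param seed master seed; sub-generators use seed, seed+1, seed+2,
#'   seed+3
#' @param design a [candidate_design()]
#' @param n_samples samples in the FPKM matrix
#' @param n_specific planted specific transcripts (taken from the
#'   planted survivors in id order)
#' @return list with `genome`, `annotation`, `candidates`, `sequences`,
#'   `hits`, `expression` (matrix), `truth` (list `candidates`,
#'   `expression`)
#' @export
default_fixture <- function(seed = 42L, design = candidate_design(),
                            n_samples = 4L, n_specific = 20L) {
  g <- generate_genome(seed = seed)
  cand <- generate_candidates(g, design = design, seed = seed + 1L)
  hits <- generate_hit_tables(cand$truth, seed = seed + 2L)

  survivors <- cand$truth$transcript_id[cand$truth$planted_removal == "survivor"]
  spec_ids <- utils::head(sort(survivors), n_specific)
  samples <- sprintf("S%d", seq_len(n_samples))
  spec <- data.frame(transcript_id = spec_ids,
                     focal_sample = samples[(seq_along(spec_ids) - 1L) %%
                                              n_samples + 1L])
  gene_ids <- as.character(S4Vectors::mcols(g$annotation$genes)$gene_id)
  expr <- generate_expression(c(sort(cand$truth$transcript_id), gene_ids),
                              n_samples = n_samples,
                              design = expression_design(specific = spec),
                              seed = seed + 3L,
                              sample_names = samples)
  list(genome = g$genome, annotation = g$annotation,
       candidates = cand$candidates, sequences = cand$sequences,
       hits = hits, expression = expr$matrix,
       truth = list(candidates = cand$truth, expression = expr$truth))
}
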