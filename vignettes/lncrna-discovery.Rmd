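---
title: "Identifying and annotating lncRNAs from assembled transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and annotating lncRNAs from assembled transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscout)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts of at least 200 nt that do
not encode protein — conventionally, that carry no open reading frame
longer than 100 amino acids. In a non-model organism the starting material
is a set of transcript models assembled from RNA-Seq (GTF), a reference
gene annotation, the transcript sequences, and per-sample FPKM abundances.
`lncscout` turns these into a lncRNA catalogue in five steps: a
coding-potential **filter cascade**, a seven-way **positional
classification** against the annotation, **structure** summaries,
**expression** calls (sample-specific and differential), and positional +
co-expression **association** with protein-coding genes.

Everything is driven by plain data: the package never runs an aligner,
assembler, BLAST, HMMER, Infernal or a coding-potential classifier. Where
such evidence is needed it is consumed as a hit table (TSV with
`query_id`, `subject`, `evalue`, `score` and a declared kind), so the
cascade is reproducible from files alone.

## The filter cascade

Candidates pass six ordered steps; a transcript is attributed to the
first step that rejects it, so the per-step removal lists partition the
rejected set and the final catalogue equals the intersection of the
individual keeps (order affects attribution only, never membership —
this is tested).

| step | rule | default |
|---|---|---|
| size | spliced length ≥ `min_len_nt` AND exons ≥ `min_exons` | 200 nt, 2 (inclusive) |
| protein_db | no protein-database hit with e-value < cutoff | 10⁻³ (strict <) |
| orf | longest ORF ≤ `max_orf_nt` | 300 nt ("longer than" is strict) |
| coding_potential | score ≤ `cpc_max_score` | −1 (inclusive ≤) |
| domain | no protein-domain hit below cutoff | 10⁻³ |
| ncrna_family | no structured-ncRNA family hit below cutoff | 10⁻³ |

The inclusive/strict directions at the boundaries matter and are pinned
by tests: a 200-nt two-exon transcript is kept, a longest ORF of exactly
300 nt is kept, a protein hit at e-value exactly 10⁻³ does not
disqualify, and a coding-potential score of exactly −1 is retained.
Candidates absent from a homology table are kept; candidates absent from
the coding-potential table follow a configurable policy whose default is
*drop with a warning* — the conservative choice when the goal is a
high-confidence catalogue. No published e-value cutoffs exist for the
domain and family scans, so both default to 10⁻³ and are exposed in
`cascade_config()`.

## ORF definition

`find_orfs()` scans all six frames (three offsets on the forward
sequence, three on the reverse complement). An ORF is **ATG-initiated
and stop-terminated**, its length counted in nucleotides including the
stop codon; within a frame the first ATG after the previous stop opens
the next ORF, and ATGs nested inside a reported ORF are not reported
separately. This start-to-stop definition matches the 100-amino-acid
convention (300 nt = 99 codons + stop). Because a truncated transcript
model can end mid-ORF, ATG runs that reach the sequence end without a
stop are reported as *open-ended* and, by default, count toward the
longest-ORF statistic — again the conservative direction for coding
exclusion; both this and a stop-to-stop mode (`mode = "stop_stop"`) are
switchable for sensitivity analysis. Codons containing `N` match
neither ATG nor a stop. The scanner is verified against an independent
brute-force enumerator on 1,000 random sequences.

## Positional classification

Each candidate gets exactly one of seven categories, decided by fixed
precedence: shared splice junction (an intron identical to a reference
intron, same strand) → exonic sense → exonic antisense → intronic sense
→ intronic antisense → intergenic → unclassified. Design choices worth
stating:

* *Exonic* requires ≥ 1 bp exon–exon overlap, not mere gene-span
  overlap; *intronic* requires the whole candidate inside a single
  intron of a single reference transcript (the antisense variant mirrors
  this; a partial-overlap reading is available via
  `intronic_partial = TRUE`).
* Junction sharing outranks exonic overlap because an identical splice
  junction is the strongest structural evidence of a relationship; the
  evidence column retains all contributing genes so users can re-rank.
* Unstranded candidates (`*`, as produced by unstranded assemblies) can
  only be intergenic or unclassified — every other category depends on
  strand.
* Candidates whose full intron chain matches a reference isoform are
  flagged *known* by `flag_known_transcripts()` and excluded before
  classification: the pipeline looks for novel transcripts.

Loci are connected components of "≥ 1 bp exon–exon overlap on the same
scaffold, any strand" (union-find; verified against a graph-components
oracle), with ids assigned in (scaffold, start) order so results are
input-order invariant.

## Structure summaries

Transcript length means the spliced (exonic) length — the RNA the cell
sees — with the genomic span also reported. Isoform distinctness is
keyed on the exact intron chain, so ragged 5′/3′ ends do not inflate
isoform counts. The alternative-splicing fraction is computed **per
locus** (loci with ≥ 2 distinct isoforms / all loci); a per-transcript
reading exists in the literature, but the per-locus one answers the
question "how many genes produce multiple isoforms".

## Expression calls

A transcript is *sample-specific* only in its single highest sample
(ties disqualify). Two rules are evaluated there: FPKM > 3 in the focal
sample and < 1 everywhere else; and focal ≥ 10 × the largest other
value. The published criteria list both rules without stating their
combination, so the default is the stricter `AND` (matching the small
specific sets such analyses report), with `OR` a switch. The fold rule
compares against the **maximum** of the other samples — the strictest
reading — and floors the divisor at ε = 0.01 FPKM to avoid dividing by
zero.

Differential calls use Welch's two-sided t-test on
log2(FPKM + 0.1) with Benjamini–Hochberg q-values over all tested
transcripts, calling at p < 0.05 AND q < 0.05 (both cutoffs are config
keys, since published threshold sentences mix a p < 0.05 test with a
p < 0.01/q < 0.05 rule). This deliberately replaces the assembler
suite's internal dispersion model, which is out of scope here; the
`method` column flags it, and with fewer than two replicates per group
the caller degrades to flagged fold-change-only calls. Type-I control is
tested on null simulations.

Pearson co-expression is computed on **raw FPKM** (the identities
r(x, x) = 1 and r on exactly reversed profiles = −1 hold only there;
`log_scale = TRUE` is available), with the two-sided p-value from
t = r·√((n−2)/(1−r²)) and the *strong* label at |r| > 0.8. Constant
profiles have undefined r and are flagged rather than labelled. The
heatmap-style export clusters 1 − r distances with average linkage.

## Neighbour association

Distances are measured between the lncRNA span and the gene span (the
scale at which such distances are reported), as the gap between closed
intervals: `start(downstream) − end(upstream) − 1`, so a gene ending at
1,000 and a lncRNA starting at 1,501 are 500 bp apart. The adjacency
window (default 10 kb) is inclusive at the boundary. Each lncRNA yields
all overlapping genes (distance 0) plus at most the nearest
non-overlapping gene per side, reported out to 50 kb — wider than the
calling window because biologically interesting neighbours occur tens of
kb away. `relation` states where the gene lies relative to the lncRNA
along the gene's own transcription direction.

## The synthetic study

`default_fixture()` builds the whole study deterministically from one
seed: a 5-scaffold, 2-Mb genome with 40 multi-exon genes separated by
≥ 25 kb (at least twice the neighbour window, so intergenic placements
are unambiguous); 460 candidates — 40 per positional category with
unambiguous geometry (e.g. intronic plants keep ≥ 50 bp margins inside
one intron; junction plants copy exactly one intron of a ≥ 3-exon gene)
plus 30 per cascade-removal fate — and a 4-sample FPKM matrix with 20
planted specific lncRNAs. Planted "coding" sequences embed a 450-nt
ORF; "noncoding" sequences are rejection-sampled until their longest
six-frame ORF is ≤ 210 nt, using the package's own scanner (analytic
stop placement across six overlapping frames is intractable, and the
scanner itself is independently verified). These sizes keep the full
suite and an end-to-end run in minutes on one CPU while giving every
category ≥ 10 exemplars.

Planted co-expression draws each pair from a shared **fixed,
empirically standardised latent profile** across samples — a
deterministic tissue-like gradient — with loadings √r and independent
noise, so the pair correlation equals the target in expectation. Using
a fixed profile rather than resampling it per replicate reflects how
co-expression arises in real designs (a shared response to the sample
panel) and concentrates the sample correlation near the target. Planted
differential transcripts shift one group by a stated log2 fold change
with within-group SD `noise_sd` (default 0.25 log2 units; analyses that
need a clean single-signal demonstration use 0.1).

What the generator does **not** emulate: real nucleotide composition
(hexamer structure, GC skew), ragged or mis-assembled transcript ends,
genuine read-sampling noise in FPKM, and any real biology behind the
expression patterns. Passing the planted-truth tests therefore shows
the *logic* of the pipeline is correct under unambiguous geometry — not
that real data will be as clean; borderline real cases land in
`UNCLASSIFIED` by design rather than being forced into a category.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed throughout (the GRanges/GTF
  convention), so import/export is the identity and interval arithmetic
  is delegated to IRanges.
* Empty inputs return empty, well-typed results (an empty catalogue
  yields an empty summary with `NA` AS fraction, not an error).
* Ties: argmax ties disqualify specificity; locus ids break ties by
  (scaffold, start, end).
* Divisions are guarded: fold rule ε = 0.01 FPKM; |r| = 1 maps to
  p = 0 directly; two constant groups compare as p = 1 when equal.
* All generators take an explicit seed and set the RNG; identical seeds
  give byte-identical files.

## A worked run

```{r, eval = FALSE}
fx <- default_fixture(seed = 42)
res <- run_pipeline(fx$candidates, fx$sequences, fx$annotation, fx$hits,
                    expr = fx$expression, out_dir = "run")
res$filter_report      # 460 -> 280 in six audited steps
res$class_table        # category x sample counts
res$structure          # exon histogram, lengths, AS fraction
head(res$links)        # neighbours with r, p, strength
```

The `analysis/` directory of the source repository runs the same study
as five narrated scripts (simulate → filter → classify/features →
expression → association), and `scripts/acceptance.R` recomputes the
headline quantities from scratch into JSON.

## Limitations

The cascade can only be as good as the hit tables it is given; it does
not compute homology or coding potential itself. The t-test replaces a
count-based dispersion model and should be read accordingly at small
replicate numbers. Four samples are enough to demonstrate specificity
calling but far too few for calibrated co-expression discovery — the
strong/weak labels become meaningful at n ≳ 10. Enhancer- or
promoter-derived lncRNA subtypes are not called; the seven positional
categories are exhaustive but deliberately coarse.
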