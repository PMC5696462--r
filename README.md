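# lncscout

Discovery and positional annotation of long non-coding RNAs (lncRNAs)
from assembled transcriptomes.

Given transcript models (GTF), a reference gene annotation (GTF/GFF3),
transcript sequences (FASTA) and a transcripts × samples FPKM matrix
(TSV), `lncscout`:

1. **Filters** candidates through an ordered coding-potential cascade —
   spliced length ≥ 200 nt and ≥ 2 exons; no protein-database hit at
   e-value < 10⁻³; longest six-frame ORF ≤ 300 nt (ATG→stop, stop
   included); coding-potential score ≤ −1; no protein-domain hit; no
   structured-ncRNA family hit — with every removal attributed to
   exactly one step in an auditable report. Homology and
   coding-potential evidence is consumed as plain hit tables; the
   package never executes the underlying search tools.
2. **Classifies** each surviving lncRNA into one of seven positional
   categories against the annotation, by fixed precedence: shared
   splice junction ▸ exonic sense ▸ exonic antisense ▸ intronic sense ▸
   intronic antisense ▸ intergenic ▸ unclassified; and clusters
   transcripts into loci by exonic overlap.
3. **Profiles structure**: exon-count histogram, spliced-length
   comparison with protein-coding genes, loci per scaffold, and the
   alternative-splicing fraction (loci with ≥ 2 distinct intron
   chains).
4. **Calls expression patterns**: sample-specific lncRNAs (FPKM > 3 in
   the focal sample and < 1 elsewhere, AND ≥ 10-fold over the
   next-highest sample), differential expression (Welch t on
   log2(FPKM + 0.1), Benjamini–Hochberg q-values, p < 0.05 and
   q < 0.05), and Pearson co-expression with |r| > 0.8 labelled strong.
5. **Associates** lncRNAs with protein-coding genes: span overlaps,
   nearest gene per side with gap distance
   `start(downstream) − end(upstream) − 1`, an inclusive 10-kb
   adjacency window, and co-expression attached to every link.

A seeded synthetic-data generator (`default_fixture()`) emulates every
input — toy genome, planted candidates with known class/ORF/fate,
homology tables, FPKM matrix — so the whole pipeline is testable
against known truth.

## Worked example

```r
library(lncscout)

fx  <- default_fixture(seed = 42)          # synthetic study, 460 candidates
res <- run_pipeline(fx$candidates, fx$sequences, fx$annotation, fx$hits,
                    expr = fx$expression, out_dir = "run")
res$filter_report
#> lncRNA candidate cascade:
#>              step n_in n_kept n_removed
#>              size  460    430        30
#>        protein_db  430    400        30
#>               orf  400    370        30
#>  coding_potential  370    340        30
#>            domain  340    310        30
#>      ncrna_family  310    280        30
#> final candidates: 280
```

Each row is one cascade step: 460 candidates enter, 30 planted
failures are removed at each step, and 280 planted lncRNAs survive —
all of them at exactly the step their construction dictates.
Downstream, `res$classes` recovers all 280 planted positional
categories (40 per category), `res$structure` reports 280 transcripts
in 214 loci with a 16.4% per-locus alternative-splicing fraction, and
`res$specific` calls exactly the 20 planted sample-specific lncRNAs
with zero false calls:

```r
table(res$classes$category)
#>     JUNCTION_SHARE       EXONIC_SENSE   EXONIC_ANTISENSE     INTRONIC_SENSE
#>                 40                 40                 40                 40
#> INTRONIC_ANTISENSE         INTERGENIC       UNCLASSIFIED
#>                 40                 40                 40
sum(res$specific$specific)
#> [1] 20
```

`run/` then contains the per-step filter report, the lncRNA GTF/FASTA
subsets, classification and locus tables, structure summaries,
expression calls, annotated neighbour links and a `manifest.json` with
config, versions and per-stage counts. Re-running with the same seed
reproduces every file byte for byte.

The same study, narrated step by step, lives in `analysis/01_simulate.R`
through `analysis/05_association.R`; each script prints what it found
and writes its tables under `results/`.

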