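#!/usr/bin/env Rscript
# Build the synthetic study: a toy multi-scaffold genome with multi-exon
# coding genes, ~460 planted candidate transcripts (every positional
# category and every cascade-removal fate represented), homology /
# coding-potential tables, and a 4-sample FPKM matrix with 20 planted
# sample-specific lncRNAs. All files land under results/fixture/.

suppressPackageStartupMessages(library(lncscout))

seed <- 42L
out <- "results/fixture"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- default_fixture(seed = seed)

write_fasta(fx$genome, file.path(out, "genome.fa"))
write_gtf(fx$annotation$tx, file.path(out, "reference.gtf"))
write_gtf(fx$candidates, file.path(out, "candidates.gtf"))
write_fasta(fx$sequences, file.path(out, "candidates.fa"))
write_expression(fx$expression, file.path(out, "fpkm.tsv"))
for (kind in names(fx$hits)) {
  write_hit_table(fx$hits[[kind]], file.path(out, paste0(kind, "_hits.tsv")))
}
write.table(fx$truth$candidates, file.path(out, "truth_candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fx$truth$expression, file.path(out, "truth_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- fx$truth$candidates
cat("Synthetic study written to", out, "(seed", seed, ")\n")
cat(sprintf("  genes: %d on %d scaffolds\n",
            length(fx$annotation$genes), length(fx$genome)))
cat(sprintf("  candidates: %d (%d planted survivors)\n", nrow(tr),
            sum(tr$planted_removal == "survivor")))
cat("  planted removal fates:\n")
print(table(tr$planted_removal))
cat("  planted positional classes (survivors):\n")
print(table(tr$planted_class[tr$planted_removal == "survivor"]))
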