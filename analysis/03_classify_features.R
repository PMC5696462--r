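#!/usr/bin/env Rscript
# Classify the surviving lncRNA candidates against the reference
# annotation, cluster them into loci, and summarise their gene structure.

suppressPackageStartupMessages(library(lncscout))

fix <- "results/fixture"
out <- "results/classify"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lnc <- read_gtf("results/filter/lncrna.gtf", kind = "candidate")
ref <- read_gtf(file.path(fix, "reference.gtf"), kind = "reference")
expr <- read_expression(file.path(fix, "fpkm.tsv"))

known <- flag_known_transcripts(lnc, ref)
cat(sprintf("known reference isoforms excluded: %d\n", sum(known)))
if (any(known)) lnc <- tx_subset(lnc, names(known)[!known])

classes <- classify_transcripts(lnc, ref)
loci <- cluster_loci(lnc)
write.table(merge(classes, loci$members), file.path(out, "classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(loci$loci, file.path(out, "loci.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
tab <- classification_table(classes, expr = expr)
write.table(data.frame(category = rownames(tab), tab, check.names = FALSE),
            file.path(out, "classification_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nlncRNA counts by positional category and sample:\n")
print(tab)

truth <- read.delim(file.path(fix, "truth_candidates.tsv"))
m <- merge(classes, truth[, c("transcript_id", "planted_class")])
cat(sprintf("\nPlanted classes recovered: %.1f%% (%d/%d)\n",
            100 * mean(as.character(m$category) == m$planted_class),
            sum(as.character(m$category) == m$planted_class), nrow(m)))

s <- summarize_structure(lnc, coding = ref$tx, loci = loci)
write.table(s$exon_count_hist, file.path(out, "exon_count_hist.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$length_summary, file.path(out, "length_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$scaffold_hist, file.path(out, "scaffold_locus_hist.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
iso <- isoform_report(lnc, loci)
write.table(iso, file.path(out, "isoforms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_bed12(lnc, file.path(out, "lncrna.bed"),
            category = setNames(as.character(classes$category),
                                classes$transcript_id))

two_exon <- s$exon_count_hist$fraction[s$exon_count_hist$n_exons == 2]
cat(sprintf("\nStructure: %d lncRNAs in %d loci; %.1f%% two-exon;\n",
            s$n_transcripts, s$n_loci, 100 * two_exon))
cat(sprintf("mean spliced length %.0f bp (lncRNA) vs %.0f bp (coding);\n",
            s$length_summary$mean_spliced_len[1],
            s$length_summary$mean_spliced_len[2]))
cat(sprintf("%.1f%% of loci alternatively spliced (top locus: %d isoforms).\n",
            100 * s$as_fraction, max(iso$n_isoforms)))
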