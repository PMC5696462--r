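#!/usr/bin/env Rscript
# Position + co-expression association between the recovered lncRNAs and
# the reference protein-coding genes: overlaps, nearest neighbours within
# 10 kb, and Pearson co-expression over the shared samples.

suppressPackageStartupMessages(library(lncscout))

fix <- "results/fixture"
out <- "results/association"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lnc <- read_gtf("results/filter/lncrna.gtf", kind = "candidate")
ref <- read_gtf(file.path(fix, "reference.gtf"), kind = "reference")
expr <- read_expression(file.path(fix, "fpkm.tsv"))

links <- find_neighbors(lnc, ref, window_bp = 10000L, max_report_bp = 50000L)
links <- annotate_links(links, expr, strong_cut = 0.8)
write.table(links, file.path(out, "neighbor_links.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ovl <- overlap_report(lnc, ref)
write.table(ovl, file.path(out, "overlap_geometry.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Neighbour links: %d total; %d overlap a gene; %d within 10 kb\n",
            nrow(links), sum(links$relation == "overlap"),
            sum(links$within_window)))
cat("Relations:\n")
print(table(links$relation))
cat(sprintf("Overlap geometry: %d lncRNA-gene pairs (%d touching exons, %d intronic)\n",
            nrow(ovl), sum(ovl$part == "exon"), sum(ovl$part == "intron")))
cat(sprintf("Gap distances for non-overlap links: median %.0f bp (range %d-%d)\n",
            median(links$distance_bp[links$relation != "overlap"]),
            min(links$distance_bp[links$relation != "overlap"]),
            max(links$distance_bp[links$relation != "overlap"])))
strong <- links[!is.na(links$strong) & links$strong, ]
cat(sprintf("Strongly co-expressed links (|r| > 0.8 over %d samples): %d\n",
            ncol(expr), nrow(strong)))
cat("(With 4 samples the correlation estimate is noisy; strong labels here\n")
cat(" demonstrate the mechanics, not a calibrated discovery rate.)\n")
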