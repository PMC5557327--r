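#!/usr/bin/env Rscript
# Detect gene clusters (>= 2 family genes with intergenic gaps < 10 kb) on
# the simulated annotation and check them against the planted truth.

library(crpevol)

ann <- read_gff("results/simdata/annotation.gff3")
clusters <- detect_clusters(ann, max_gap_bp = 10000)
stats <- cluster_summary(clusters, family_total = nrow(ann))

truth <- read.delim("results/simdata/truth_clusters.tsv")
canon <- function(v) paste(sort(v), collapse = ",")
want <- vapply(split(truth$gene_id, truth$structure_id), canon, character(1))
got <- vapply(strsplit(clusters$member_ids, ","), canon, character(1))

write.table(clusters, "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(stats, "results/cluster_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("found", nrow(clusters), "clusters covering", stats$n_clustered_genes,
    "genes (", stats$fraction_clustered, "% of the family)\n")
cat("planted clusters recovered exactly:", sum(want %in% got), "of",
    length(want), "\n")
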