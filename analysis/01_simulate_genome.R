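#!/usr/bin/env Rscript
# Simulate the study genome: 4 chromosomes x 35 genes with planted clusters,
# tandem arrays and collinear segments, plus the homolog-pair table and the
# ground-truth ledger. All downstream drivers read the files written here.

library(crpevol)

seed <- 20260923
sim <- simulate_genome(n_chromosomes = 4, genes_per_chromosome = 35,
                       n_clusters = 5, cluster_gap_bp = 2000,
                       n_tandem_arrays = 3, n_collinear_segments = 3,
                       segment_length_anchors = 6, seed = seed)
paths <- write_synthetic_genome(sim, "results/simdata")

cat("simulated", nrow(sim$annotation), "genes on",
    length(unique(sim$annotation$chromosome)), "chromosomes;",
    nrow(sim$pairs), "homolog pairs\n")
cat("planted:", length(sim$truth$planted_clusters), "clusters,",
    length(sim$truth$planted_tandem_arrays), "tandem arrays,",
    length(sim$truth$planted_collinear_segments), "collinear segments\n")
cat("wrote:", paste(basename(paths), collapse = ", "),
    "under results/simdata\n")
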