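#!/usr/bin/env Rscript
# Single-cell QC and consensus clustering: filter cells on nGene/nCount and
# doublet score, embed on 50 PCs of the highly variable genes, run a
# 20-seed Louvain ensemble at resolution 2, merge runs by DBSCAN over the
# ensemble-disagreement distance, and rescue outliers with a random
# forest. Reports agreement with the generator's true labels.

suppressMessages(library(planastra))

out <- "results/02_cluster"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- make_worm(worm_config(seed = 1))   # same worm as 01_simulate
cells <- simulate_counts(truth, "cells")
qc <- qc_filter(cells$counts, cells$meta$doublet_score)
write.table(qc$report, file.path(out, "qc_report.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("cells retained:", nrow(qc$counts), "of", nrow(cells$counts), "\n")
print(qc$report)

norm <- normalize_log(qc$counts)
hvg <- select_hvg(norm, 1000)
graph <- embed_and_graph(norm, hvg, n_pcs = 50, n_neighbors = 15)
cons <- cluster_consensus(graph, resolution = 2, n_runs = 20,
                          min_samples = 20, seed = 2)

labels <- data.frame(cell_id = rownames(qc$counts), label = cons$label,
                     status = cons$status,
                     true_type = cells$meta$true_type[qc$keep])
write.table(labels, file.path(out, "consensus_labels.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

keep <- cons$status != "dropped"
cat(sprintf("consensus clusters: %d  dropped: %.2f%%  ARI vs truth: %.3f\n",
            length(unique(cons$label[keep])), 100 * cons$dropped_fraction,
            mclust::adjustedRandIndex(cons$label[keep],
                                      labels$true_type[keep])))

markers <- rank_markers(norm[keep, ], cons$label[keep])
write.table(markers[markers$adjusted_p < 0.05 & markers$log_fold_change > 0, ],
            file.path(out, "cluster_markers.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
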