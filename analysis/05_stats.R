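#!/usr/bin/env Rscript
# Inference: hypergeometric A-P enrichment of cell types, ligand-receptor
# communication strength with a permutation null, NB-GLM spatial
# colocalization of the planted pairs, and background-matched module
# scoring of the planted domain program.

suppressMessages(library(planastra))

out <- "results/05_stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- make_worm(worm_config(seed = 1))   # same worm as 01_simulate
spot_sim <- simulate_counts(truth, "spots")
norm <- normalize_log(spot_sim$counts)
spots <- sample_spots(truth)

seg <- segment_ap_axis(spots, 7, anterior = c(0, 150))
mk <- rank_markers(norm, paste0("seg", seg$segment))
sel <- mk$adjusted_p < 0.05 & mk$log_fold_change > 0
enr <- hypergeom_enrichment(split(truth$markers$gene, truth$markers$type),
                            split(mk$gene[sel], mk$group[sel]),
                            colnames(norm))
write.table(enr$p, file.path(out, "enrichment_p.tsv"), sep = "\t",
            quote = FALSE)
cat("anterior (seg1) enrichment p, neuron:",
    signif(enr$p["neuron", "seg1"], 3),
    " posterior (seg7):", signif(enr$p["neuron", "seg7"], 3), "\n")

cells <- simulate_counts(truth, "cells")
qc <- qc_filter(cells$counts, cells$meta$doublet_score)
cnorm <- normalize_log(qc$counts)
db <- truth$planted_lr[, c("ligand", "receptor")]
comm <- communication_strength(cnorm, cells$meta$true_type[qc$keep], db,
                               n_perm = 200, seed = 3)
write.table(comm$scores, file.path(out, "communication.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

coloc <- do.call(rbind, lapply(seq_len(nrow(truth$planted_lr)), function(i) {
  cr <- colocalization_degree(spot_sim$counts, truth$planted_lr$ligand[i],
                              truth$planted_lr$receptor[i])
  data.frame(ligand = cr$ligand, receptor = cr$receptor,
             planted = truth$planted_lr$slope[i], slope = cr$slope,
             se = cr$se, p = cr$p_value, model = cr$model)
}))
write.table(coloc, file.path(out, "colocalization.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("colocalization degrees (planted -> fitted):\n")
print(coloc[, c("ligand", "receptor", "planted", "slope", "se")])

ms <- module_score(norm, truth$domain_genes, seed = 4)
ab <- estimate_abundance(spot_sim$counts, truth$signatures)
cm <- module_celltype_correlation(matrix(ms, ncol = 1,
                                         dimnames = list(NULL, "domain")),
                                  ab)
write.table(data.frame(spot_id = spots$spot_id, score = ms,
                       domain = truth$domain_map),
            file.path(out, "module_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
ins <- truth$domain_map == 1
cat(sprintf("domain module score: %.2f inside vs %.2f outside (%.0fx the outside SD)\n",
            mean(ms[ins]), mean(ms[!ins]),
            (mean(ms[ins]) - mean(ms[!ins])) / sd(ms[!ins])))
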