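#!/usr/bin/env Rscript
# Build the synthetic regenerating worm: three serial 10-um sections of an
# elliptical body, seven major cell types with A-P gradients, neoblasts
# calibrated to 27% of somatic cells, planted markers, a pharynx-like
# spatial domain, and two colocalized ligand-receptor pairs. Emits the
# 10x-style count triplets, the spot table, and the ground truth used by
# the later stages.

suppressMessages(library(planastra))

out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- worm_config(seed = 1)
truth <- make_worm(cfg)
spots <- sample_spots(truth)
spot_sim <- simulate_counts(truth, "spots")
cell_sim <- simulate_counts(truth, "cells")

write_spots_csv(spots, file.path(out, "spots.csv"))
write_counts_mtx(spot_sim$counts, file.path(out, "spot_counts"))
write_counts_mtx(cell_sim$counts, file.path(out, "cell_counts"))
write.table(truth$markers, file.path(out, "planted_markers.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(spot_id = spots$spot_id, truth$spot_composition,
                       domain = truth$domain_map, check.names = FALSE),
            file.path(out, "truth_composition.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("sections: %d  spots: %d  cells: %d\n", cfg$n_sections,
            nrow(spots), cfg$n_cells))
cat(sprintf("median UMIs/spot: %.0f  median UMIs/cell: %.0f\n",
            median(Matrix::rowSums(spot_sim$counts)),
            median(Matrix::rowSums(cell_sim$counts))))
cat(sprintf("mean neoblast fraction: %.3f (target %.2f)\n",
            mean(truth$spot_composition[, "neoblast"]),
            cfg$neoblast_fraction))
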