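# planastra

Planarians regenerate any missing body part from a resident stem-cell
population (neoblasts, ~25–30% of somatic cells). Mapping how their seven
major cell types — neoblast, neuron, muscle, gut, secretory, epidermal,
parenchymal — redistribute in space during regeneration takes serial-section
spatial transcriptomics plus matched single-cell RNA-seq, and a chain of
bespoke computational stages to fuse them into a 3D atlas. **planastra**
implements that chain as a tested R package for computational biologists
working with Visium-style serial sections:

- **Consensus clustering** of single cells: an ensemble of Louvain runs at
  resolution 2, merged by DBSCAN over the pairwise ensemble-disagreement
  ("Hamming") distance `d(u,v) = #{runs where labels differ}/n_runs` with
  eps 0.1, and outliers rescued by a random forest on the PCs when the top
  class probability exceeds 0.5.
- **Geometry**: closed-form rigid (Procrustes) section alignment; the 3D
  spatial neighbor network (same-section links at distance < 150,
  adjacent-section links at < 100); non-overlapping tiling of all sections
  onto a midpoint-enriched base array; equal-width anterior–posterior
  segmentation (10 or 7 segments).
- **Spot annotation**: per-spot cell-type abundance by variance-weighted
  NNLS on reference signatures scaled to 30 cells/spot (a transparent
  stand-in for Bayesian deconvolution, same contract), top-3 co-occurrence
  counting, and a 60×60 histology-patch classifier with class balancing,
  stratified fivefold CV, and pseudo-label transfer to unsequenced
  sections.
- **Inference**: exact upper-tail hypergeometric enrichment
  `P(X ≥ k | N, K, n)` of cell types along the A-P axis (α = 0.05);
  ligand–receptor communication strength (mean ligand in sender × mean
  receptor in receiver, permutation null); the spatial **colocalization
  degree** — the slope *b* of the negative binomial GLM
  `receptor ~ exp(a + b·ligand)` fitted per spot; and background-matched
  gene module scores with module–cell-type correlations.

Because the study's sequencing data and histology are external, the package
ships a **synthetic worm generator** (`worm_config()`, `make_worm()`) that
plants known composition gradients, markers, a spatial domain, rigid
section placements and colocalized ligand–receptor pairs, at the study's
depths (median 21,388 UMIs/spot, 3,991 UMIs/cell, 10 µm sections, neoblast
fraction 0.27). Every stage is validated against that ground truth.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on the
synthetic worm and write their tables under `results/`. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cluster.R
Rscript analysis/05_stats.R
```

prints (seed 1):

```
sections: 3  spots: 300  cells: 2000
median UMIs/spot: 21250  median UMIs/cell: 4016
mean neoblast fraction: 0.270 (target 0.27)

cells retained: 1851 of 2000
consensus clusters: 7  dropped: 0.00%  ARI vs truth: 0.998

anterior (seg1) enrichment p, neuron: 7.71e-89  posterior (seg7): 1
colocalization degrees (planted -> fitted):
  ligand receptor planted     slope        se
1  g0441    g0442     0.8 0.6725775 0.1312368
2  g0443    g0444     0.5 0.5317830 0.1425723
domain module score: 1.74 inside vs -0.07 outside (23x the outside SD)
```

Reading this: QC removed exactly the planted low-complexity cells and
doublets; the 20-run Louvain ensemble recovered the seven planted types
essentially perfectly (adjusted Rand index 0.998) while dropping no cells;
the anterior-planted neuronal type is hypergeometrically enriched only in
the anterior segment; both planted ligand–receptor slopes are recovered
within their standard errors on 300 spots; and the planted domain's module
score separates inside from outside spots by 23 outside-SDs.

`run_pipeline(run_config(...), out_dir)` executes the same chain as one
orchestrated, manifest-tracked run whose outputs are byte-reproducible
from the config and seed.

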