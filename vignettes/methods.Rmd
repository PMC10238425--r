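---
title: "Methods: reconstructing a planarian spatial atlas from serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing a planarian spatial atlas from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

planastra implements the computational stages needed to turn serial-section
spatial transcriptomics of a regenerating planarian, plus matched single-cell
RNA-seq, into a 3D cell-type atlas: consensus clustering of cells, rigid
section alignment and a 3D spatial neighbor network, per-spot cell-type
deconvolution and co-occurrence, histology-patch cell-type imputation,
anterior-posterior (A-P) enrichment testing, ligand-receptor statistics, and
spatial gene-module scoring. Every stage is exercised against a synthetic
worm whose ground truth is known, so the pipeline is testable without any
sequencing data. This vignette records the models, the defaults, and the
design choices a maintainer would want explained.

## The synthetic worm

`worm_config()`/`make_worm()` build a virtual animal. The body is an
ellipse per section (1000 x 300 um by default, three serial sections at
10 um), discretized into a 50 um spot grid. The paper-scale targets the
generator honours are the seven major planarian cell types (neoblast,
neuron, muscle, gut, secretory, epidermal, parenchymal), a whole-worm
neoblast fraction of 0.27 (calibrated exactly by rescaling the neoblast
gradient and renormalizing), median depths of 21,388 UMIs per spot and
3,991 UMIs per cell, and A-P composition gradients (neurons
anterior-heavy, gut mid-body, parenchyma posterior by default).

Counts are negative binomial around signature mixtures. The per-cell NB
size is 0.5 (strongly overdispersed, as raw single-cell counts are);
`Inf` gives the Poisson limit. A spot pools ~30 cells, and the NB size of
a sum of independent NB variables with a common mean profile is additive,
so spot counts are drawn with size `0.5 * cells_per_spot = 15`. This
pooling is what makes spot-level deconvolution a well-posed problem at all:
at single-cell dispersion the per-gene multiplicative noise (~140% CV)
swamps mixture information regardless of depth.

Signatures share a lognormal baseline across types; each type's markers
(60 per type at fold change 4) are boosted only in that type, so the
planted fold change is exact by construction. Sixty markers out of 1,200
genes reflects how transcriptionally distinct the major planarian cell
types are — whole expression programs, not a handful of genes; with much
weaker signatures the types are not separable by any clustering method and
nothing downstream is learnable. A pharynx-like central disc is planted as
a spatial domain whose 20 genes are 8-fold up inside it (anatomical
domains express tens of near-exclusive genes). Two ligand-receptor pairs
are planted by regenerating the receptor column as
`NB(exp(a + slope * lignorm), size = 2)` against the same log-normalized
ligand covariate the colocalization fit uses, with slopes 0.8 and 0.5.

Each section also receives a recorded rigid placement (rotation up to 15
degrees plus translation; section 0 is the reference), so alignment
recovery is testable at zero noise. Histology is stood in for by
`render_patches()`: each 60 x 60 patch encodes its class as a mean
intensity and a class-frequency sine texture, corrupted by a per-patch
offset and pixel noise with SD (class spacing)/snr. High snr gives
linearly separable classes; snr near zero drives the Bayes rate to chance.
No histological realism is claimed — the generator only guarantees *some*
learnable class signal whose strength is controlled.

What passing tests on this generator do **not** show about real data:
section-to-section batch effects, spatially varying capture efficiency,
segmentation errors, real H&E morphology, and ambient RNA are all absent.
The generator validates the algorithms, not the biology.

## Preprocessing and consensus clustering

QC keeps cells with nGene >= 500, nCount <= 30,000, nGene <= 6,000 and
doublet score <= 0.5, attributing each removal to the first failed rule in
that order. The doublet score is an input: the generator's truth flag by
default, or a clearly labelled co-expression heuristic for real data (an
external simulation-based scorer is out of scope). Normalization is
`ln(count / total * 10,000 + 1)`; the scale factor is the community
convention since the bare formula leaves it open. HVG selection ranks
mean-binned dispersion on the back-transformed scale (the log-scale
alternative changes little on the generator); PCA uses the top 50 PCs of
3,000 HVGs (clamped for small universes) and the SNN graph uses Jaccard
overlap of 15-NN sets pruned below 1/15.

Consensus clustering runs Louvain at resolution 2 under `n_runs` seeds
(100 at atlas scale; tests scale to 20), computes the pairwise
ensemble-disagreement distance — the fraction of runs in which two cells
get different labels, the only reading of a Hamming distance over run
labels that is invariant to arbitrary per-run label ids — and applies
DBSCAN (eps 0.1, min_samples 100 at atlas scale, scaled with dataset
size) over that precomputed metric, with neighborhoods `d <= eps` and the
point itself counted, the scikit-learn convention. DBSCAN outliers are
rescued by a 500-tree random forest on the PCs of consensus-labelled
cells; an outlier is rescued only if its top class probability strictly
exceeds 0.5, otherwise dropped. Ties at exactly 0.5 drop, per the strict
inequality.

## Geometry

Section alignment is closed-form least-squares rotation-plus-translation
(orthogonal Procrustes restricted to proper rotations) on landmark pairs;
on noiseless landmarks it is exact to machine precision. The 3D neighbor
network links same-section spots at distance < 150 and adjacent-section
spots at in-plane distance < 100, strictly; the thresholds are unitless
array-scale defaults and the coordinate unit must be declared in the run
configuration to avoid silent mismatches. Between-section distances are
measured in the aligned x-y plane (z is fixed by sectioning). Tiling maps
every spot of every section to its nearest node of the base array (the
base section's spots plus half-pitch midpoints; exact ties go to the
lower node index, deterministically), so total score mass is conserved.
A-P segmentation projects spots on the first principal axis (or an
explicit axis), oriented by a caller-supplied anterior landmark — the
orientation cannot be inferred from coordinates alone — and cuts the
range into 10 (intact) or 7 (regenerating) equal-width bins, the last bin
right-closed.

## Annotation

Per-spot abundance is an iteratively reweighted nonnegative least-squares
fit of the depth-normalized spot profile on depth-normalized type
signatures: after an unweighted pass, genes are weighted by the inverse
square root of their NB variance (dispersion estimated per spot by method
of moments) so that highly expressed genes with large multiplicative
noise do not dominate. Coefficients are rescaled to the expected 30 cells
per spot. This is a transparent stand-in for a Bayesian deconvolution
model with the same input/output contract — it is not that model, and is
logged as such. Co-occurrence counts, per spot, every unordered pair
among the top-3 most abundant types (ties broken by type order).

The patch classifier is a multinomial logistic model on pixel summary
features (mean, SD, texture power spectrum): deterministic given the
seed, no accelerator needed, and satisfying the same contract (patch in,
probability vector summing to 1) a convolutional model would. Training
balances classes by capped downsampling and reports stratified fivefold
cross-validation. New sections without sequencing are labelled by the
adjacent section's model; predictions above 0.5 (the same convention as
outlier rescue; the confidence threshold is otherwise unstated) re-enter
training as pseudo-labels for a configurable number of rounds. In-section
imputation targets are half-pitch midpoints: every spot spawns +x and +y
midpoints including the trailing edge, so a 2x2 grid yields 8.

## Inference

A-P enrichment is an exact upper-tail hypergeometric test of the overlap
between type markers and segment-specific genes (p < 0.05 flags
enrichment); the tail sum is computed from log binomial coefficients, and
is tested against a frozen exact-rational oracle and an independent exact
implementation over every N <= 60. Communication strength is mean
normalized ligand expression in the sender times mean normalized receptor
expression in the receiver, summed over pairs for a population pair;
significance uses a one-sided label-permutation null (1,000 permutations
by default) with BH correction — permutation count and sidedness are
package choices where the procedure left them open. The spatial
colocalization degree of a ligand-receptor pair is the slope of a
negative binomial GLM (log link) of raw receptor counts on log-normalized
ligand expression, fitted with ML-estimated dispersion and a logged
Poisson fallback when the dispersion diverges; receptor-on-ligand is the
default orientation with `both = TRUE` reporting the reverse, since the
orientation is not dictated by the model. Module scores are mean module
expression minus expression-bin-matched controls (24 bins, 100 controls
per gene, the convention behind the standard scoring function), and
module-type correlations are Pearson correlations against deconvolved
abundances.

## Numerical choices and degenerate inputs

Zero-total units normalize to all-zero rows with a warning. Constant
genes are never selected as HVGs (relative variance floor 1e-10).
Rank-sum marker tests fall back to the exact distribution where
`wilcox.test` does (small untied samples) and use mid-ranks with a normal
approximation otherwise; groups under 3 units are excluded with a
warning. NNLS rank deficiency (near-identical signatures) warns and
reports the merged types. DBSCAN with min_samples above the unit count
flags everything as outlier, with a warning rather than an error. The
rescue forest's size (500 trees) is a package default — decisions on the
test suite are insensitive between 100 and 500 trees. All randomness
flows from one seed through fixed stage offsets, so changing one stage's
draws cannot perturb another's.

## Problem sizes

The bundled analyses and tests run the generator at ~300 spots x 3
sections x 1,200 genes and 500-3,000 cells, Louvain ensembles of 6-20
runs with min_samples 8-20, and 100-replicate simulations for the GLM
recovery studies; these sizes were chosen so the whole suite re-runs
comfortably on a laptop while leaving every statistical property
measurable. Atlas-scale defaults (100 runs, min_samples 100) remain the
package defaults.

## Known limitations

The deconvolution stand-in ignores gene-gene covariance and batch
structure; the patch model cannot represent morphology beyond intensity
and texture statistics; graph-attention domain extraction, Bayesian
deconvolution, autocorrelation-based module detection, RNA velocity and
GO enrichment are deliberately out of scope (the package builds their
inputs where relevant). Real-data thresholds (150/100 graph distances,
QC cutoffs) are exposed as parameters and their units must be supplied by
the caller.
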