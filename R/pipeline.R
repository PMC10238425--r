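# Formats, configuration, and end-to-end orchestration.

#' Read / write 10x-style MatrixMarket count triplets
#'
#' `write_counts_mtx` writes matrix.mtx (coordinate integer), genes.tsv and
#' barcodes.tsv into `dir`; `read_counts_mtx` reads them back (gzipped
#' variants are handled transparently). The matrix is stored
#' genes x barcodes on disk, the 10x convention, and returned
#' units x genes.
#'
#' @param cm sparse units x genes count matrix with dimnames.
#' @param dir directory.
#' @return `read_counts_mtx`: the sparse units x genes matrix.
#' @export
write_counts_mtx <- function(cm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(cm), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(cm), file.path(dir, "genes.tsv"))
  writeLines(rownames(cm), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  pick <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing file: ", base, " in ", dir)
  }
  m <- Matrix::readMM(pick("matrix.mtx"))
  genes <- readLines(pick("genes.tsv"))
  barcodes <- readLines(pick("barcodes.tsv"))
  if (nrow(m) != length(genes))
    stop("dimension mismatch: matrix.mtx declares ", nrow(m),
         " genes but genes.tsv has ", length(genes))
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: matrix.mtx declares ", ncol(m),
         " barcodes but barcodes.tsv has ", length(barcodes))
  m <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(m) <- list(barcodes, genes)
  m
}

#' Read / write the spot coordinate table
#'
#' CSV with columns barcode, section, array_row, array_col, x_um, y_um,
#' z_um (micrometre coordinates).
#'
#' @param spots a spot table (internal column names).
#' @param path CSV path.
#' @return `read_spots_csv`: the spot table with internal column names.
#' @export
write_spots_csv <- function(spots, path) {
  out <- data.frame(barcode = spots$spot_id, section = spots$section,
                    array_row = spots$array_row, array_col = spots$array_col,
                    x_um = spots$x, y_um = spots$y, z_um = spots$z)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  d <- read.csv(path)
  need <- c("barcode", "section", "x_um", "y_um", "z_um")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("spot CSV missing columns: ",
                            paste(missing, collapse = ", "))
  data.frame(spot_id = d$barcode, section = d$section,
             array_row = d$array_row %||% NA_integer_,
             array_col = d$array_col %||% NA_integer_,
             x = d$x_um, y = d$y_um, z = d$z_um)
}

#' Pipeline configuration with atlas defaults
#'
#' Collects every stage's parameters, with the atlas conventions as
#' defaults: QC 500/30,000/6,000/0.5; 3,000 HVGs; 50 PCs; Louvain
#' resolution 2 with 100 runs; DBSCAN eps 0.1 / min_samples 100; rescue
#' probability 0.5; graph thresholds 150 (within) / 100 (between); 30
#' cells per spot; top-3 co-occurrence; 60-pixel patches with fivefold CV;
#' 10 or 7 A-P segments; alpha 0.05. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L, coordinate_unit = "um",
    qc_min_genes = 500, qc_max_counts = 30000, qc_max_genes = 6000,
    qc_doublet_max = 0.5,
    n_hvg = 3000, n_pcs = 50, n_neighbors = 15,
    resolution = 2, n_runs = 100, eps = 0.1, min_samples = 100,
    rescue_prob = 0.5, rescue_trees = 500,
    within_thresh = 150, between_thresh = 100,
    cells_per_spot = 30, cooccur_k = 3,
    patch_px = 60L, patch_snr = 5, cv_folds = 5,
    n_segments = 10L, alpha = 0.05,
    n_perm = 1000, module_bins = 24, module_ctrl = 100,
    worm = list()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (is.null(cfg$coordinate_unit) || !nzchar(cfg$coordinate_unit))
    stop("coordinate_unit must be declared")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full synthetic-atlas pipeline
#'
#' Executes simulate -> QC -> normalize/HVG/PCA/SNN -> consensus cluster
#' -> spatial graph and A-P segmentation -> deconvolution and
#' co-occurrence -> enrichment, colocalization and module scoring, writes
#' each stage's tables under `out_dir`, and returns (and writes) a
#' manifest recording every parameter, every stage seed, and the MD5
#' checksum of every artifact, sufficient to reproduce deterministic
#' outputs byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written as manifest.yaml).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(parameters = unclass(config), stages = list(),
                  artifacts = list())
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  wcfg <- do.call(worm_config, c(config$worm, list(seed = config$seed)))
  truth <- run_stage("simulate", function() make_worm(wcfg))
  spots <- sample_spots(truth)
  spot_sim <- run_stage("simulate", function() simulate_counts(truth, "spots"))
  cell_sim <- run_stage("simulate", function() simulate_counts(truth, "cells"))
  write_spots_csv(spots, file.path(out_dir, "spots.csv"))
  write_counts_mtx(spot_sim$counts, file.path(out_dir, "spot_counts"))
  write_counts_mtx(cell_sim$counts, file.path(out_dir, "cell_counts"))

  qc <- run_stage("qc", function() {
    # thresholds scale with the synthetic gene universe
    qc_filter(cell_sim$counts, cell_sim$meta$doublet_score,
              min_genes = config$qc_min_genes,
              max_counts = config$qc_max_counts,
              max_genes = config$qc_max_genes,
              doublet_max = config$qc_doublet_max)
  })
  write.table(qc$report, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  norm <- normalize_log(qc$counts)
  hvg <- select_hvg(norm, min(config$n_hvg, ncol(norm)))
  graph <- run_stage("embed", function()
    embed_and_graph(norm, hvg, config$n_pcs, config$n_neighbors))

  cons <- run_stage("cluster", function()
    cluster_consensus(graph, resolution = config$resolution,
                      n_runs = config$n_runs,
                      seeds = stage_seed(config$seed, "ensemble") +
                        seq_len(config$n_runs),
                      eps = config$eps, min_samples = config$min_samples,
                      prob_threshold = config$rescue_prob,
                      n_trees = config$rescue_trees,
                      seed = stage_seed(config$seed, "rescue")))
  labels_df <- data.frame(cell_id = rownames(qc$counts),
                          label = cons$label, status = cons$status)
  write.table(labels_df, file.path(out_dir, "consensus_labels.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  edges <- run_stage("spatial", function()
    build_3d_graph(spots, config$within_thresh, config$between_thresh))
  write.table(edges, file.path(out_dir, "spatial_graph.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  seg <- run_stage("spatial", function()
    segment_ap_axis(spots, config$n_segments, anterior = c(0, 0)))
  write.table(data.frame(spot_id = spots$spot_id, segment = seg$segment),
              file.path(out_dir, "segments.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  ab <- run_stage("annotate", function()
    estimate_abundance(spot_sim$counts, truth$signatures,
                       config$cells_per_spot))
  write.table(data.frame(spot_id = rownames(ab$abundance), ab$abundance),
              file.path(out_dir, "abundance.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  co <- top_k_cooccurrence(ab, config$cooccur_k)
  write.table(co, file.path(out_dir, "cooccurrence.tsv"), sep = "\t",
              quote = FALSE)

  stats_out <- run_stage("stats", function() {
    spot_norm <- normalize_log(spot_sim$counts)
    seg_groups <- paste0("seg", seg$segment)
    seg_markers <- rank_markers(spot_norm, seg_groups)
    seg_sets <- split(seg_markers$gene[seg_markers$adjusted_p < 0.05 &
                                         seg_markers$log_fold_change > 0],
                      seg_markers$group[seg_markers$adjusted_p < 0.05 &
                                          seg_markers$log_fold_change > 0])
    type_sets <- split(truth$markers$gene, truth$markers$type)
    enr <- hypergeom_enrichment(type_sets, seg_sets,
                                colnames(spot_sim$counts), config$alpha)
    coloc <- lapply(seq_len(nrow(truth$planted_lr)), function(i)
      colocalization_degree(spot_sim$counts, truth$planted_lr$ligand[i],
                            truth$planted_lr$receptor[i]))
    ms <- module_score(spot_norm, truth$domain_genes,
                       n_bins = config$module_bins,
                       n_ctrl = config$module_ctrl,
                       seed = stage_seed(config$seed, "module"))
    list(enrichment = enr, coloc = coloc, module = ms)
  })
  write.table(stats_out$enrichment$p, file.path(out_dir, "enrichment_p.tsv"),
              sep = "\t", quote = FALSE)
  coloc_df <- do.call(rbind, lapply(stats_out$coloc, function(cr)
    data.frame(ligand = cr$ligand, receptor = cr$receptor, slope = cr$slope,
               se = cr$se, p_value = cr$p_value, model = cr$model)))
  write.table(coloc_df, file.path(out_dir, "colocalization.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(spot_id = spots$spot_id,
                         module_score = stats_out$module),
              file.path(out_dir, "module_scores.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest", files)]
  manifest$stages <- list(
    simulate = list(seed = config$seed,
                    spot_seed = stage_seed(config$seed, "simulate_spots"),
                    cell_seed = stage_seed(config$seed, "simulate_cells")),
    cluster = list(n_runs = config$n_runs, resolution = config$resolution,
                   eps = config$eps, min_samples = config$min_samples,
                   rescue_prob = config$rescue_prob,
                   dropped_fraction = cons$dropped_fraction),
    spatial = list(within = config$within_thresh,
                   between = config$between_thresh,
                   n_segments = config$n_segments),
    annotate = list(cells_per_spot = config$cells_per_spot,
                    deconvolution = "nnls_standin",
                    cooccur_k = config$cooccur_k),
    stats = list(alpha = config$alpha)
  )
  manifest$artifacts <- as.list(tools::md5sum(files))
  names(manifest$artifacts) <- basename(names(manifest$artifacts))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
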