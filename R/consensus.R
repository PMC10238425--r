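# Consensus clustering: Louvain ensemble -> Hamming-distance DBSCAN ->
# random-forest rescue of outliers.

#' Run an ensemble of Louvain clusterings
#'
#' Louvain community detection on the SNN graph at a fixed resolution,
#' repeated under different random seeds. Within-run label ids are
#' arbitrary; only co-assignment structure matters downstream.
#'
#' @param graph an `embedding_graph` (or a sparse symmetric adjacency).
#' @param resolution Louvain resolution (default 2).
#' @param n_runs ensemble size (default 100).
#' @param seeds integer vector of length `n_runs` (default 1..n_runs).
#' @return list of class `ensemble_assignments`: `runs` (units x n_runs
#'   integer matrix), `resolution`, `seeds`, `modularity` per run.
#' @export
run_ensemble <- function(graph, resolution = 2, n_runs = 100,
                         seeds = seq_len(n_runs)) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (length(seeds) != n_runs) stop("seeds must have length n_runs")
  adj <- if (inherits(graph, "embedding_graph")) graph$snn else graph
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  n <- igraph::vcount(g)
  runs <- matrix(NA_integer_, n, n_runs)
  mods <- numeric(n_runs)
  for (j in seq_len(n_runs)) {
    cl <- with_seed(seeds[j],
                    igraph::cluster_louvain(g, resolution = resolution))
    runs[, j] <- igraph::membership(cl)
    mods[j] <- max(cl$modularity)
  }
  rownames(runs) <- rownames(adj)
  out <- list(runs = runs, resolution = resolution, seeds = seeds,
              modularity = mods)
  class(out) <- "ensemble_assignments"
  out
}

#' Pairwise ensemble disagreement (Hamming) distance
#'
#' d(u, v) = fraction of runs in which u and v receive different labels.
#' Invariant to any per-run relabeling and to run order.
#'
#' @param runs units x n_runs integer label matrix.
#' @return dense symmetric matrix in \[0,1\] with zero diagonal.
#' @export
hamming_distance <- function(runs) {
  runs <- as.matrix(runs)
  n <- nrow(runs)
  acc <- matrix(0, n, n)
  for (j in seq_len(ncol(runs))) {
    acc <- acc + outer(runs[, j], runs[, j], "!=")
  }
  d <- acc / ncol(runs)
  dimnames(d) <- list(rownames(runs), rownames(runs))
  d
}

# DBSCAN over a precomputed distance matrix (neighborhood d <= eps,
# min_samples includes the point itself, matching the common scikit-learn
# convention the consensus procedure assumes). No installed package offers
# DBSCAN on a precomputed metric, so this is implemented directly.
dbscan_precomputed <- function(d, eps, min_samples) {
  n <- nrow(d)
  if (min_samples > n) {
    warning("min_samples exceeds the number of units; everything is an outlier")
    return(list(labels = rep(NA_integer_, n), core = logical(n)))
  }
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (is.na(labels[q])) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nb[[q]][is.na(labels[nb[[q]]])])
      }
    }
  }
  list(labels = labels, core = core)
}

#' Density-based consensus of an ensemble
#'
#' DBSCAN over the pairwise ensemble-disagreement distance; units in no
#' dense region are flagged outliers (label NA) for downstream rescue.
#'
#' @param ens an `ensemble_assignments`.
#' @param eps DBSCAN radius on the disagreement fraction (default 0.1).
#' @param min_samples DBSCAN density threshold (default 100; scale it with
#'   dataset size — the default presumes ~5e4 units).
#' @return list of class `consensus_labels`: `label` (integer, NA =
#'   outlier), `is_core`, `eps`, `min_samples`.
#' @export
hamming_consensus <- function(ens, eps = 0.1, min_samples = 100) {
  stopifnot(inherits(ens, "ensemble_assignments"))
  d <- hamming_distance(ens$runs)
  db <- dbscan_precomputed(d, eps, min_samples)
  out <- list(label = db$labels, is_core = db$core, eps = eps,
              min_samples = min_samples, unit_ids = rownames(ens$runs))
  class(out) <- "consensus_labels"
  out
}

#' Rescue consensus outliers with a random forest
#'
#' Fits a random forest on the PCs of consensus-labeled units and predicts
#' each outlier's class; outliers whose top class probability exceeds
#' `prob_threshold` (strictly) are rescued with that label, the rest are
#' dropped.
#'
#' @param pcs units x k PC matrix (same row order as the consensus).
#' @param consensus a `consensus_labels`.
#' @param prob_threshold rescue threshold on the predicted probability
#'   (default 0.5, strict).
#' @param n_trees random forest size (default 500).
#' @param seed RNG seed for the forest.
#' @return list of class `consensus_labels` with `label`, `status`
#'   (core/rescued/dropped per unit), and `dropped_fraction`.
#' @export
rescue_outliers <- function(pcs, consensus, prob_threshold = 0.5,
                            n_trees = 500, seed = 1L) {
  stopifnot(inherits(consensus, "consensus_labels"))
  lab <- consensus$label
  status <- ifelse(is.na(lab), "dropped", "core")
  out_idx <- which(is.na(lab))
  classes <- sort(unique(lab[!is.na(lab)]))
  if (length(out_idx) > 0) {
    if (length(classes) < 2) {
      warning("fewer than 2 consensus classes; all outliers dropped")
    } else {
      rf <- with_seed(seed, randomForest::randomForest(
        x = pcs[!is.na(lab), , drop = FALSE],
        y = factor(lab[!is.na(lab)]), ntree = n_trees))
      pr <- predict(rf, pcs[out_idx, , drop = FALSE], type = "prob")
      top <- max.col(pr, ties.method = "first")
      topp <- pr[cbind(seq_len(nrow(pr)), top)]
      rescue <- topp > prob_threshold
      lab[out_idx[rescue]] <- as.integer(colnames(pr)[top[rescue]])
      status[out_idx[rescue]] <- "rescued"
    }
  }
  res <- list(label = lab, status = status,
              dropped_fraction = mean(status == "dropped"),
              unit_ids = consensus$unit_ids)
  class(res) <- "consensus_labels"
  res
}

#' Full consensus clustering of an embedding graph
#'
#' Convenience wrapper: [run_ensemble()] then [hamming_consensus()] then
#' [rescue_outliers()].
#'
#' @inheritParams run_ensemble
#' @inheritParams hamming_consensus
#' @inheritParams rescue_outliers
#' @return the rescued `consensus_labels`.
#' @export
cluster_consensus <- function(graph, resolution = 2, n_runs = 100,
                              seeds = seq_len(n_runs), eps = 0.1,
                              min_samples = 100, prob_threshold = 0.5,
                              n_trees = 500, seed = 1L) {
  ens <- run_ensemble(graph, resolution, n_runs, seeds)
  cons <- hamming_consensus(ens, eps, min_samples)
  rescue_outliers(graph$pcs, cons, prob_threshold, n_trees, seed)
}
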