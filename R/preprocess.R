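# Single-cell QC, normalization, HVG selection, PCA/SNN graph, markers.

#' Per-unit QC covariates
#'
#' @param counts sparse units x genes count matrix.
#' @return data.frame with nGene (genes detected) and nCount (total UMIs).
#' @export
qc_metrics <- function(counts) {
  data.frame(unit_id = rownames(counts),
             nGene = Matrix::rowSums(counts > 0),
             nCount = Matrix::rowSums(counts),
             row.names = rownames(counts))
}

#' Filter low-quality cells and doublets
#'
#' Retains cells with nGene >= `min_genes`, nCount <= `max_counts`,
#' nGene <= `max_genes`, and doublet score <= `doublet_max`. A cell failing
#' several rules is attributed to the first failed rule in that order.
#'
#' @param counts sparse cells x genes count matrix.
#' @param doublet_score numeric in \[0,1\] per cell (e.g. the generator's
#'   truth flag, an external scorer, or [doublet_score_heuristic()]).
#' @param min_genes,max_counts,max_genes,doublet_max thresholds; defaults
#'   are the atlas conventions (500 / 30,000 / 6,000 / 0.5).
#' @return list with `counts` (filtered), `keep` (logical), and `report`
#'   (data.frame of cells removed per rule, in attribution order).
#' @export
qc_filter <- function(counts, doublet_score, min_genes = 500,
                      max_counts = 30000, max_genes = 6000,
                      doublet_max = 0.5) {
  if (missing(doublet_score) || is.null(doublet_score))
    stop("doublet_score is required: supply the generator truth flag, an ",
         "external scorer's output, or doublet_score_heuristic()")
  if (length(doublet_score) != nrow(counts))
    stop("doublet_score length must match the number of cells")
  m <- qc_metrics(counts)
  fail <- cbind(low_nGene = m$nGene < min_genes,
                high_nCount = m$nCount > max_counts,
                high_nGene = m$nGene > max_genes,
                doublet = doublet_score > doublet_max)
  keep <- rowSums(fail) == 0
  # first-failed-rule attribution
  first <- apply(fail, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  report <- data.frame(rule = colnames(fail),
                       removed = vapply(seq_len(4), function(j)
                         sum(first == j, na.rm = TRUE), integer(1)))
  if (!any(keep)) warning("qc_filter removed every cell")
  list(counts = counts[keep, , drop = FALSE], keep = keep, report = report)
}

#' Co-expression doublet heuristic
#'
#' A transparent stand-in for an external doublet scorer, for data without
#' a truth flag: scores each cell by co-expression of mutually exclusive
#' type markers (fraction of marker sets of distinct types that are both
#' detected, rescaled to \[0,1\]). Not equivalent to a simulation-based
#' scorer; use it only when nothing better is available.
#'
#' @param counts cells x genes counts.
#' @param markers data.frame(gene, type) of mutually exclusive marker sets.
#' @return numeric score in \[0,1\] per cell.
#' @export
doublet_score_heuristic <- function(counts, markers) {
  types <- unique(markers$type)
  det <- vapply(types, function(tt) {
    g <- intersect(markers$gene[markers$type == tt], colnames(counts))
    as.numeric(Matrix::rowSums(counts[, g, drop = FALSE] > 0) >
                 0.5 * length(g))
  }, numeric(nrow(counts)))
  co <- rowSums(det)
  pmin(1, pmax(0, (co - 1) / max(1, length(types) - 1)))
}

#' Depth-normalize and log-transform counts
#'
#' value(i,g) = ln(count(i,g) / nCount(i) * scale + 1). Rows with zero
#' total are left all-zero with a warning.
#'
#' @param counts sparse units x genes counts.
#' @param scale library-size scale factor (default 10,000).
#' @return sparse matrix of normalized values.
#' @export
normalize_log <- function(counts, scale = 10000) {
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " unit(s) with zero total count left all-zero")
    tot[tot == 0] <- 1
  }
  out <- methods::as(Matrix::Diagonal(x = scale / tot) %*% counts,
                     "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Select highly variable genes by binned dispersion
#'
#' Mean and dispersion (variance/mean) are computed on the
#' back-transformed normalized values; genes are binned by mean expression
#' (20 bins) and dispersions z-scored within bins; the top `n` genes by
#' normalized dispersion are returned. Constant genes are never selected.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param n number of genes (default 3000; clamped with a warning).
#' @return character vector of gene ids.
#' @export
select_hvg <- function(norm, n = 3000) {
  if (n > ncol(norm)) {
    warning("n exceeds gene count; clamped to ", ncol(norm))
    n <- ncol(norm)
  }
  x <- expm1(norm)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- pmax(0, ex2 - mu^2) * nrow(x) / max(1, nrow(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(quantile(mu, seq(0, 1, length.out = 21))),
              include.lowest = TRUE)
  zs <- stats::ave(disp, bins, FUN = function(d) {
    s <- stats::mad(d)
    if (s == 0) s <- sd(d)
    if (is.na(s) || s == 0) return(rep(0, length(d)))
    (d - median(d)) / s
  })
  zs[v <= 1e-10 * pmax(mu^2, 1e-12)] <- -Inf   # constant genes are never variable
  ord <- order(zs, decreasing = TRUE)
  colnames(norm)[ord[seq_len(n)]]
}

#' PCA embedding and shared-nearest-neighbor graph
#'
#' PCA on the centered HVG submatrix; kNN in PC space (Euclidean); SNN
#' edge weight = Jaccard overlap of kNN sets, pruned below `prune`.
#'
#' @param norm normalized matrix.
#' @param hvg_ids genes to embed on.
#' @param n_pcs number of PCs (default 50; clamped to the rank with warning).
#' @param n_neighbors kNN size (default 15, excluding self).
#' @param prune Jaccard floor below which SNN edges are dropped (default 1/15).
#' @return list of class `embedding_graph`: `pcs` (units x k), `snn`
#'   (sparse symmetric, zero diagonal), `hvg_ids`, `knn` (index matrix).
#' @export
embed_and_graph <- function(norm, hvg_ids, n_pcs = 50, n_neighbors = 15,
                            prune = 1 / 15) {
  if (nrow(norm) < 2) stop("need at least 2 units")
  x <- as.matrix(norm[, hvg_ids, drop = FALSE])
  maxrank <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > maxrank) {
    warning("n_pcs exceeds rank; clamped to ", maxrank)
    n_pcs <- maxrank
  }
  pcs <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  rownames(pcs) <- rownames(norm)

  n <- nrow(pcs)
  k <- min(n_neighbors, n - 1L)
  d2 <- as.matrix(stats::dist(pcs))
  diag(d2) <- Inf
  knn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))

  # SNN: Jaccard of kNN sets (self included, the usual convention)
  inc <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                              j = as.integer(t(cbind(seq_len(n), knn))),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(inc)
  jac <- shared / (2 * (k + 1L) - shared)
  jac <- methods::as(jac, "CsparseMatrix")
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  dimnames(jac) <- list(rownames(norm), rownames(norm))
  out <- list(pcs = pcs, snn = jac, hvg_ids = hvg_ids, knn = knn)
  class(out) <- "embedding_graph"
  out
}

#' One-vs-rest marker detection
#'
#' Two-sided Wilcoxon rank-sum of each gene in each group against all
#' other units, on normalized values, with Benjamini-Hochberg adjustment
#' across genes within each group. Log fold change is the natural log of
#' the ratio of back-transformed means (pseudocount 1e-9). Groups with
#' fewer than 3 units are excluded with a warning.
#'
#' @param norm normalized matrix (units x genes).
#' @param groups factor/character of group labels per unit.
#' @param min_frac_in optional filter: keep rows detected in at least this
#'   fraction of the group (default 0, no filter).
#' @return data.frame (gene, group, log_fold_change, fraction_in,
#'   fraction_out, p_value, adjusted_p), sorted by group then p.
#' @export
rank_markers <- function(norm, groups, min_frac_in = 0) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("groups excluded (fewer than 3 units): ",
            paste(small, collapse = ", "))
  }
  use <- setdiff(names(tab), small)
  if (length(use) < 2) stop("need at least 2 groups with >= 3 units")
  x <- as.matrix(norm)
  res <- lapply(use, function(g) {
    ing <- groups == g
    xin <- x[ing, , drop = FALSE]
    xout <- x[!ing, , drop = FALSE]
    p <- vapply(seq_len(ncol(x)), function(j) {
      suppressWarnings(wilcox.test(xin[, j], xout[, j])$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1   # constant gene: no evidence
    mean_in <- colMeans(expm1(xin))
    mean_out <- colMeans(expm1(xout))
    data.frame(gene = colnames(x), group = g,
               log_fold_change = log((mean_in + 1e-9) / (mean_out + 1e-9)),
               fraction_in = colMeans(xin > 0),
               fraction_out = colMeans(xout > 0),
               p_value = p,
               adjusted_p = p.adjust(p, "BH"))
  })
  out <- do.call(rbind, res)
  out <- out[out$fraction_in >= min_frac_in, , drop = FALSE]
  out[order(out$group, out$p_value), ]
}
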