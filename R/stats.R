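# Inferential stages: A-P hypergeometric enrichment, ligand-receptor
# communication strength, NB-GLM spatial colocalization degree, and
# background-matched gene module scoring.

#' Exact upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing
#' at least k marker-gene overlaps given a universe of N genes, K type
#' markers, and n segment markers. Computed by the exact tail sum of
#' binomial-coefficient terms (no normal approximation).
#'
#' @param k observed overlap.
#' @param N universe size.
#' @param K first set size.
#' @param n second set size.
#' @return the upper-tail probability (1 when k <= 0).
#' @export
hypergeom_tail <- function(k, N, K, n) {
  if (K > N || n > N) stop("set sizes exceed the universe")
  if (k > min(K, n)) stop("overlap exceeds min(K, n): inconsistent input")
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Cell-type enrichment along the A-P axis
#'
#' Upper-tail hypergeometric test of the overlap between each cell type's
#' marker genes and each axis segment's specific genes, against a common
#' gene universe. p < alpha is flagged as significant enrichment.
#'
#' @param type_markers named list of character vectors (marker genes per
#'   cell type), or a MarkerTable data.frame with columns gene, group.
#' @param segment_markers same, per axis segment.
#' @param universe character vector of all genes (or an integer size, in
#'   which case marker sets are assumed consistent with it).
#' @param alpha significance level (default 0.05).
#' @return list of class `enrichment_result`: `p` (types x segments),
#'   `overlap`, `mask` (p < alpha), `alpha`.
#' @export
hypergeom_enrichment <- function(type_markers, segment_markers, universe,
                                 alpha = 0.05) {
  as_sets <- function(m) {
    if (is.data.frame(m)) split(m$gene, m$group) else m
  }
  ts <- as_sets(type_markers)
  ss <- as_sets(segment_markers)
  if (is.character(universe)) {
    allg <- unique(universe)
    bad <- setdiff(unlist(c(ts, ss)), allg)
    if (length(bad)) stop("markers outside the universe: ",
                          paste(head(bad, 5), collapse = ", "))
    N <- length(allg)
  } else {
    N <- as.integer(universe)
  }
  p <- matrix(NA_real_, length(ts), length(ss),
              dimnames = list(names(ts), names(ss)))
  ov <- p
  for (i in seq_along(ts)) {
    for (j in seq_along(ss)) {
      k <- length(intersect(ts[[i]], ss[[j]]))
      ov[i, j] <- k
      p[i, j] <- hypergeom_tail(k, N, length(unique(ts[[i]])),
                                length(unique(ss[[j]])))
    }
  }
  out <- list(p = p, overlap = ov, mask = p < alpha, alpha = alpha)
  class(out) <- "enrichment_result"
  out
}

#' Ligand-receptor communication strength between populations
#'
#' score(pair, sender -> receiver) = mean normalized ligand expression in
#' the sender population x mean normalized receptor expression in the
#' receiver population; the strength between two populations combines
#' (sums) the scores of all pairs. Significance per pair and direction is
#' assessed by a one-sided label-permutation null with Benjamini-Hochberg
#' correction across pairs.
#'
#' @param expr normalized expression (units x genes).
#' @param labels population label per unit (>= 2 populations).
#' @param lrdb data.frame(ligand, receptor) of candidate pairs; genes must
#'   exist in `expr`.
#' @param n_perm permutations for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list of class `communication_result`: `scores` (pair, sender,
#'   receiver, score, p_value, adjusted_p), `combined` (sender x receiver
#'   matrix of summed scores).
#' @export
communication_strength <- function(expr, labels, lrdb, n_perm = 1000,
                                   seed = 1L) {
  labels <- as.character(labels)
  pops <- sort(unique(labels))
  if (length(pops) < 2) stop("need at least 2 populations")
  genes <- unique(c(lrdb$ligand, lrdb$receptor))
  missing <- setdiff(genes, colnames(expr))
  if (length(missing)) stop("ligand/receptor genes absent from expression: ",
                            paste(head(missing, 5), collapse = ", "))
  x <- as.matrix(expr[, genes, drop = FALSE])

  pop_means <- function(lab) {
    m <- rowsum(x, lab) / as.vector(table(lab)[sort(unique(lab))])
    m
  }
  pm <- pop_means(labels)
  grid <- expand.grid(pair = seq_len(nrow(lrdb)), sender = pops,
                      receiver = pops, stringsAsFactors = FALSE)
  obs <- mapply(function(pr, s, r) pm[s, lrdb$ligand[pr]] * pm[r, lrdb$receptor[pr]],
                grid$pair, grid$sender, grid$receiver)
  exceed <- numeric(nrow(grid))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pmb <- pop_means(sample(labels))
      sc <- mapply(function(pr, s, r)
        pmb[s, lrdb$ligand[pr]] * pmb[r, lrdb$receptor[pr]],
        grid$pair, grid$sender, grid$receiver)
      exceed <- exceed + (sc >= obs)
    }
  })
  pv <- (exceed + 1) / (n_perm + 1)
  scores <- data.frame(ligand = lrdb$ligand[grid$pair],
                       receptor = lrdb$receptor[grid$pair],
                       sender = grid$sender, receiver = grid$receiver,
                       score = obs, p_value = pv)
  scores$adjusted_p <- stats::ave(scores$p_value,
                                  paste(scores$sender, scores$receiver),
                                  FUN = function(p) p.adjust(p, "BH"))
  comb <- tapply(scores$score, list(scores$sender, scores$receiver), sum)
  out <- list(scores = scores, combined = comb, n_perm = n_perm)
  class(out) <- "communication_result"
  out
}

#' Spatial colocalization degree of a ligand-receptor pair
#'
#' Fits a negative binomial GLM (log link) of raw receptor counts per spot
#' on the log-normalized ligand expression; the fitted slope is the
#' spatial colocalization degree. Dispersion is re-estimated by maximum
#' likelihood during the fit; if the dispersion estimate diverges (the
#' Poisson limit) the model falls back to a Poisson GLM, with a message.
#'
#' @param spot_counts spots x genes count matrix (raw integers).
#' @param ligand,receptor gene ids.
#' @param both also fit the reversed orientation (ligand on receptor) and
#'   report it under `reversed`.
#' @return list of class `colocalization_result`: `slope`, `intercept`,
#'   `se`, `p_value`, `dispersion` (NB size; Inf for the Poisson
#'   fallback), `model` ("nb" or "poisson"), optionally `reversed`.
#' @export
colocalization_degree <- function(spot_counts, ligand, receptor,
                                  both = FALSE) {
  if (nrow(spot_counts) < 30) stop("need at least 30 spots")
  tot <- Matrix::rowSums(spot_counts)
  fit_one <- function(lig, rec) {
    ligc <- as.numeric(spot_counts[, lig])
    if (var(ligc) == 0) stop("constant ligand: slope unidentifiable")
    x <- log1p(ligc / pmax(tot, 1) * 1e4)
    y <- as.numeric(spot_counts[, rec])
    if (max(y) == 0) stop("all-zero receptor counts: nothing to fit")
    if (var(x) == 0) stop("constant ligand: slope unidentifiable")
    fit <- NULL
    model <- "nb"
    theta <- Inf
    suppressWarnings(
      fit <- tryCatch(MASS::glm.nb(y ~ x), error = function(e) NULL))
    if (!is.null(fit) && fit$converged && is.finite(fit$theta) &&
        fit$theta < 1e7) {
      theta <- fit$theta
    } else {
      message("NB dispersion estimate diverged; falling back to Poisson")
      fit <- glm(y ~ x, family = poisson())
      model <- "poisson"
    }
    sm <- summary(fit)$coefficients
    structure(list(slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   se = sm[2, 2], p_value = sm[2, 4],
                   dispersion = theta, model = model,
                   ligand = lig, receptor = rec),
              class = "colocalization_result")
  }
  out <- fit_one(ligand, receptor)
  if (both) out$reversed <- fit_one(receptor, ligand)
  out
}

#' Background-matched gene module score per spot
#'
#' Score = mean normalized expression of the module genes minus the mean
#' of expression-bin-matched control genes: genes are binned by average
#' expression into `n_bins`, and each module gene draws `n_ctrl` controls
#' from its own bin; the pooled control set is averaged per spot.
#'
#' @param expr normalized expression (spots x genes).
#' @param gene_set character vector of module genes (non-empty, present in
#'   `expr`).
#' @param n_bins expression bins (default 24).
#' @param n_ctrl control genes drawn per module gene (default 100, with
#'   replacement).
#' @param seed RNG seed for the control draws.
#' @return numeric score per spot.
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  if (length(gene_set) == 0) stop("empty gene set")
  missing <- setdiff(gene_set, colnames(expr))
  if (length(missing)) stop("module genes absent from the matrix: ",
                            paste(head(missing, 5), collapse = ", "))
  if (length(gene_set) > ncol(expr) / 2)
    warning("gene set exceeds half the universe; controls are degenerate")
  avg <- Matrix::colMeans(expr)
  brks <- unique(quantile(avg, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(avg, brks, include.lowest = TRUE, labels = FALSE)
  names(bin) <- colnames(expr)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  set_mean <- Matrix::rowMeans(expr[, gene_set, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(expr[, ctrl, drop = FALSE])
  as.numeric(set_mean - ctrl_mean)
}

#' Correlation between module scores and cell-type abundance
#'
#' Pearson correlation of per-spot module scores against per-spot type
#' abundances, one row per module and one column per type.
#'
#' @param scores spots x modules matrix (or a numeric vector for one
#'   module).
#' @param ab an `abundance_matrix` or spots x types matrix.
#' @return modules x types correlation matrix.
#' @export
module_celltype_correlation <- function(scores, ab) {
  m <- if (inherits(ab, "abundance_matrix")) ab$abundance else as.matrix(ab)
  s <- as.matrix(scores)
  if (nrow(s) != nrow(m)) stop("scores and abundances must cover the same spots")
  t(cor(m, s))
}
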