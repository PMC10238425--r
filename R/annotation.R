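# Spot-level annotation: NNLS cell-type abundance (a declared simplified
# stand-in for Bayesian deconvolution, same I/O contract), top-k
# co-occurrence, histology-patch classification and pseudo-label transfer.

#' Estimate per-spot cell-type abundance (NNLS stand-in)
#'
#' Nonnegative least squares of each depth-normalized spot profile on the
#' depth-normalized type signatures, rescaled so each spot's coefficients
#' sum to the expected number of cells per spot. The fit is iteratively
#' reweighted: after an unweighted pass, genes are weighted by the inverse
#' square-root of their negative-binomial variance (dispersion estimated
#' per spot by method of moments), so highly expressed genes with large
#' multiplicative noise do not dominate. This is a transparent simplified
#' stand-in for a Bayesian deconvolution model, with the same input/output
#' contract; it is logged as such.
#'
#' @param spot_counts spots x genes count matrix.
#' @param signatures types x genes nonnegative signature matrix (genes are
#'   intersected with the count matrix).
#' @param cells_per_spot expected cell abundance per spot (default 30).
#' @return list of class `abundance_matrix`: `abundance` (spots x types,
#'   rows summing to cells_per_spot), `proportions`, `residual` per spot.
#' @export
estimate_abundance <- function(spot_counts, signatures, cells_per_spot = 30) {
  genes <- intersect(colnames(spot_counts), colnames(signatures))
  if (length(genes) < 2) stop("count matrix and signatures share too few genes")
  if (nrow(signatures) < 2) stop("need signatures for at least 2 types")
  S <- t(as.matrix(signatures[, genes, drop = FALSE]))   # genes x types
  S <- sweep(S, 2, colSums(S), "/")
  # rank check: identical signatures make coefficients unidentifiable
  cc <- suppressWarnings(cor(S))
  dup <- which(upper.tri(cc) & cc > 1 - 1e-8, arr.ind = TRUE)
  if (nrow(dup)) {
    warning("near-identical signatures (coefficients split arbitrarily): ",
            paste(rownames(cc)[dup[, 1]], colnames(cc)[dup[, 2]],
                  sep = "~", collapse = ", "))
  }
  X <- as.matrix(spot_counts[, genes, drop = FALSE])
  tot <- rowSums(X)
  tot[tot == 0] <- 1
  Xn <- X / tot
  n <- nrow(Xn)
  k <- ncol(S)
  ab <- matrix(0, n, k, dimnames = list(rownames(spot_counts), colnames(S)))
  resid <- numeric(n)
  for (i in seq_len(n)) {
    y <- X[i, ]
    depth <- tot[i]
    cf <- pracma::lsqnonneg(S, Xn[i, ])$x
    for (it in 1:2) {
      mu <- pmax(as.vector(S %*% cf) * depth / max(sum(cf), 1e-12), 1e-3)
      size <- sum(mu^2) / max(sum(pmax((y - mu)^2 - mu, 0)), 1e-9)
      w <- 1 / sqrt(mu + mu^2 / size)
      fit <- pracma::lsqnonneg(S * w, y * w)
      cf <- fit$x
    }
    ab[i, ] <- cf
    resid[i] <- sqrt(fit$resid.norm)
  }
  rs <- rowSums(ab)
  prop <- ab / ifelse(rs > 0, rs, 1)
  out <- list(abundance = prop * cells_per_spot, proportions = prop,
              residual = resid, cells_per_spot = cells_per_spot)
  class(out) <- "abundance_matrix"
  out
}

#' Count top-k cell-type co-occurrence across spots
#'
#' For each spot, the k most abundant types (ties broken by type order)
#' contribute +1 to every unordered pair among them.
#'
#' @param ab an `abundance_matrix` or a spots x types matrix.
#' @param k number of top types per spot (default 3).
#' @return symmetric types x types integer count matrix with zero diagonal.
#' @export
top_k_cooccurrence <- function(ab, k = 3) {
  m <- if (inherits(ab, "abundance_matrix")) ab$abundance else as.matrix(ab)
  if (k > ncol(m)) stop("k exceeds the number of types")
  types <- colnames(m)
  co <- matrix(0L, ncol(m), ncol(m), dimnames = list(types, types))
  if (k < 2) return(co)
  for (i in seq_len(nrow(m))) {
    top <- order(m[i, ], decreasing = TRUE)[seq_len(k)]  # order(): ties keep type order
    pr <- utils::combn(sort(top), 2)
    for (j in seq_len(ncol(pr))) {
      co[pr[1, j], pr[2, j]] <- co[pr[1, j], pr[2, j]] + 1L
      co[pr[2, j], pr[1, j]] <- co[pr[2, j], pr[1, j]] + 1L
    }
  }
  co
}

#' Balance patch classes by random downsampling
#'
#' Each class is downsampled to min(class size, cap) under the given seed.
#'
#' @param patches a `patch_set` with labels.
#' @param cap_per_class maximum patches retained per class.
#' @param seed RNG seed.
#' @return the downsampled `patch_set`.
#' @export
balance_training <- function(patches, cap_per_class, seed = 1L) {
  stopifnot(inherits(patches, "patch_set"))
  lab <- patches$labels
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_along(lab), lab), function(idx) {
      if (length(idx) <= cap_per_class) idx
      else sort(sample(idx, cap_per_class))
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  subset_patches(patches, keep)
}

subset_patches <- function(patches, idx) {
  out <- patches
  out$patches <- patches$patches[idx, , , drop = FALSE]
  out$labels <- patches$labels[idx]
  out$coords <- patches$coords[idx, , drop = FALSE]
  out
}

# Pixel features summarizing a patch: mean intensity, sd, and sinusoidal
# texture power at the first `n_freq` column frequencies.
patch_features <- function(patches, n_freq = 8) {
  arr <- if (inherits(patches, "patch_set")) patches$patches else patches
  n <- dim(arr)[1]; px <- dim(arr)[3]
  phase <- 2 * pi * seq_len(px) / px
  sinb <- vapply(seq_len(n_freq), function(f) sin(f * phase), numeric(px))
  cosb <- vapply(seq_len(n_freq), function(f) cos(f * phase), numeric(px))
  t(vapply(seq_len(n), function(i) {
    p <- arr[i, , ]
    colm <- colMeans(p)
    pow <- sqrt((2 / px * as.vector(colm %*% sinb))^2 +
                (2 / px * as.vector(colm %*% cosb))^2)
    c(mean = mean(p), sd = sd(as.vector(p)), setNames(pow, paste0("f", seq_len(n_freq))))
  }, numeric(2 + n_freq)))
}

#' Train the patch cell-type classifier with stratified cross-validation
#'
#' The reference model is a multinomial logistic classifier on pixel
#' summary features (mean intensity, sd, texture power spectrum) —
#' deterministic given the seed and requiring no accelerator. Stratified
#' k-fold cross-validation reports per-fold and mean accuracy; the final
#' model is refit on all patches. Predicted class probability vectors sum
#' to 1.
#'
#' @param patches a labeled `patch_set`.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return list of class `patch_classifier`: `model`, `cv` (fold, accuracy),
#'   `cv_accuracy` (mean), `classes`, plus the stored training features.
#' @export
train_patch_classifier <- function(patches, folds = 5, seed = 1L) {
  stopifnot(inherits(patches, "patch_set"))
  lab <- factor(patches$labels)
  if (any(table(lab) < folds))
    stop("stratification error: every class needs at least `folds` patches; ",
         "reduce folds or supply more patches of: ",
         paste(names(which(table(lab) < folds)), collapse = ", "))
  feats <- patch_features(patches)
  fold_id <- with_seed(seed, {
    id <- integer(length(lab))
    for (cl in levels(lab)) {
      idx <- sample(which(lab == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  acc <- vapply(seq_len(folds), function(f) {
    fit <- fit_multinom(feats[fold_id != f, , drop = FALSE], lab[fold_id != f])
    pred <- predict_multinom(fit, feats[fold_id == f, , drop = FALSE])
    mean(colnames(pred)[max.col(pred, ties.method = "first")] ==
           as.character(lab[fold_id == f]))
  }, numeric(1))
  model <- fit_multinom(feats, lab)
  out <- list(model = model, cv = data.frame(fold = seq_len(folds),
                                             accuracy = acc),
              cv_accuracy = mean(acc), classes = levels(lab),
              features = feats, labels = lab, seed = seed)
  class(out) <- "patch_classifier"
  out
}

fit_multinom <- function(feats, labels) {
  df <- data.frame(feats)
  df$.y <- factor(labels)
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  df[seq_len(ncol(feats))] <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
  fit <- nnet::multinom(.y ~ ., df, trace = FALSE, maxit = 300,
                        MaxNWts = 5000)
  list(fit = fit, center = ctr, scale = scl, classes = levels(df$.y))
}

predict_multinom <- function(model, feats) {
  df <- data.frame(sweep(sweep(as.matrix(feats), 2, model$center), 2,
                         model$scale, "/"))
  p <- predict(model$fit, df, type = "probs")
  if (is.null(dim(p))) {   # 2-class: nnet returns P(second class)
    p <- cbind(1 - p, p)
    colnames(p) <- model$classes
  }
  p <- as.matrix(p)
  p / rowSums(p)
}

#' Predict class probabilities for new patches
#'
#' @param object a `patch_classifier`.
#' @param patches a `patch_set` (or feature matrix).
#' @param ... unused.
#' @return matrix of class probabilities (rows sum to 1).
#' @export
predict.patch_classifier <- function(object, patches, ...) {
  feats <- if (inherits(patches, "patch_set")) patch_features(patches)
           else as.matrix(patches)
  predict_multinom(object$model, feats)
}

#' Half-pitch midpoint coordinates of a spot grid
#'
#' Every spot spawns imputed locations at +pitch/2 along x and along y
#' (trailing-edge midpoints beyond the last spot included, so a 2x2 grid
#' yields 4 horizontal + 4 vertical midpoints); duplicates are removed.
#'
#' @param spots spot table of one section (columns x, y, section).
#' @param pitch grid pitch in the table's coordinate unit.
#' @return data.frame(section, x, y) of imputed coordinates.
#' @export
impute_midpoints <- function(spots, pitch) {
  h <- data.frame(section = spots$section, x = spots$x + pitch / 2, y = spots$y)
  v <- data.frame(section = spots$section, x = spots$x, y = spots$y + pitch / 2)
  out <- unique(rbind(h, v))
  rownames(out) <- NULL
  out
}

#' Impute cell types at unsequenced locations
#'
#' In-section targets (grid midpoints) are labeled by the section's own
#' classifier. A new section without sequencing information is labeled by
#' the adjacent section's model; predictions with probability above
#' `threshold` enter the training set as pseudo-labels and the model is
#' refit for `pseudo_label_rounds` rounds before the final prediction.
#'
#' @param classifier a `patch_classifier` (the adjacent section's model
#'   when `target = "new_section"`).
#' @param patches_for_targets a `patch_set` rendered at the target
#'   coordinates (labels, if present, are ignored).
#' @param target "midpoints" or "new_section".
#' @param pseudo_label_rounds rounds of pseudo-label retraining (default 1;
#'   0 = plain prediction).
#' @param threshold pseudo-label confidence cutoff (default 0.5, strict,
#'   matching the outlier-rescue convention).
#' @return data.frame(label, probability, provenance = "imputed") plus the
#'   probability matrix as attribute "prob"; the refit classifier as
#'   attribute "classifier".
#' @export
impute_unsequenced <- function(classifier, patches_for_targets,
                               target = c("midpoints", "new_section"),
                               pseudo_label_rounds = 1, threshold = 0.5) {
  target <- match.arg(target)
  if (is.null(classifier)) {
    stop(if (target == "new_section")
      "no adjacent model: a new section requires the adjacent section's classifier"
      else "classifier is required")
  }
  stopifnot(inherits(classifier, "patch_classifier"))
  feats <- patch_features(patches_for_targets)
  model <- classifier
  rounds <- if (target == "new_section") pseudo_label_rounds else 0
  if (rounds > 0) {
    for (r in seq_len(rounds)) {
      p <- predict_multinom(model$model, feats)
      top <- max.col(p, ties.method = "first")
      conf <- p[cbind(seq_len(nrow(p)), top)] > threshold
      if (!any(conf)) break
      aug_f <- rbind(model$features, feats[conf, , drop = FALSE])
      aug_l <- factor(c(as.character(model$labels),
                        colnames(p)[top[conf]]), levels = model$classes)
      model$model <- fit_multinom(aug_f, aug_l)
      model$features <- aug_f
      model$labels <- aug_l
    }
  }
  p <- predict_multinom(model$model, feats)
  top <- max.col(p, ties.method = "first")
  out <- data.frame(label = colnames(p)[top],
                    probability = p[cbind(seq_len(nrow(p)), top)],
                    provenance = "imputed")
  attr(out, "prob") <- p
  attr(out, "classifier") <- model
  out
}
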