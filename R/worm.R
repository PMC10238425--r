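#' Configuration for the synthetic worm generator
#'
#' Builds the configuration object for [make_worm()]. Defaults emulate the
#' design of a whole-worm Visium-style experiment on a regenerating
#' planarian: seven major cell types with neoblasts at ~27% of somatic
#' cells, serial 10-micron sections, spot depth near 21,388 median
#' UMIs/spot and cell depth near 3,991 median UMIs/cell, anterior-posterior
#' composition gradients, and planted colocalized ligand-receptor pairs.
#'
#' @param n_sections number of serial sections.
#' @param section_spacing section thickness in micrometres.
#' @param spot_pitch centre-to-centre spot spacing in micrometres.
#' @param body_length,body_width body axes in micrometres (anterior at x=0).
#' @param body_shape "ellipse" (default) or "rectangle".
#' @param cell_types ordered character vector of type names.
#' @param type_gradients types x anchors matrix of nonnegative weights,
#'   linearly interpolated along the A-P axis at positions
#'   `gradient_anchors`; each axis position's weights renormalize to a
#'   probability vector.
#' @param gradient_anchors axis positions (in \[0,1\]) of the gradient anchors.
#' @param neoblast_fraction target whole-worm neoblast fraction.
#' @param n_genes,markers_per_type,marker_fold_change expression universe
#'   size and marker planting; fold change must exceed 1.
#' @param n_domain_genes genes upregulated inside the planted spatial domain
#'   (default 20; anatomical domains such as the pharynx express a coherent
#'   program of tens of near-exclusive genes, hence the strong default fold).
#' @param domain_fold_change fold change of domain genes inside the domain.
#' @param median_spot_umis,median_cell_umis library-size targets.
#' @param n_cells number of simulated single cells.
#' @param dispersion negative-binomial size parameter for simulated
#'   single-cell counts (larger is less overdispersed; `Inf` gives Poisson
#'   counts). Spot counts pool `cells_per_spot` cells, and the NB size of a
#'   sum of independent NB variables is additive, so spots are drawn with
#'   size `dispersion * cells_per_spot`.
#' @param cells_per_spot nominal number of cells aggregated per spot
#'   (default 30); scales the spot-level NB size as above.
#' @param lr_pairs data.frame with columns ligand, receptor, slope: pairs
#'   whose receptor counts are regenerated as NB(exp(a + slope * ligand))
#'   so the planted spatial colocalization degree is recoverable.
#' @param lr_dispersion NB size used when planting receptor counts.
#' @param doublet_rate,lowq_rate fractions of simulated cells flagged as
#'   doublets / deliberately low-complexity.
#' @param seed integer; fully determines every generator output.
#' @return a list of class `worm_config`.
#' @export
worm_config <- function(n_sections = 3L,
                        section_spacing = 10,
                        spot_pitch = 50,
                        body_length = 1000,
                        body_width = 300,
                        body_shape = c("ellipse", "rectangle"),
                        cell_types = c("neoblast", "neuron", "muscle", "gut",
                                       "secretory", "epidermal", "parenchymal"),
                        type_gradients = NULL,
                        gradient_anchors = c(0, 0.5, 1),
                        neoblast_fraction = 0.27,
                        n_genes = 1200L,
                        markers_per_type = 60L,
                        marker_fold_change = 4,
                        n_domain_genes = 20L,
                        domain_fold_change = 8,
                        median_spot_umis = 21388,
                        median_cell_umis = 3991,
                        n_cells = 2000L,
                        dispersion = 0.5,
                        cells_per_spot = 30L,
                        lr_pairs = NULL,
                        lr_dispersion = 2,
                        doublet_rate = 0.05,
                        lowq_rate = 0.03,
                        seed = 1L) {
  body_shape <- match.arg(body_shape)
  if (length(cell_types) < 1) stop("cell_types: must name at least one type")
  if (spot_pitch <= 0) stop("spot_pitch: must be positive")
  if (body_length <= 0) stop("body_length: must be positive")
  if (body_width <= 0) stop("body_width: must be positive")
  if (section_spacing <= 0) stop("section_spacing: must be positive")
  if (n_sections < 1) stop("n_sections: must be >= 1")
  if (neoblast_fraction < 0 || neoblast_fraction > 1)
    stop("neoblast_fraction: must be in [0,1]")
  if (doublet_rate < 0 || doublet_rate > 1) stop("doublet_rate: must be in [0,1]")
  if (lowq_rate < 0 || lowq_rate > 1) stop("lowq_rate: must be in [0,1]")
  if (marker_fold_change <= 1) stop("marker_fold_change: must be > 1")
  if (median_spot_umis <= 0) stop("median_spot_umis: must be positive")
  if (median_cell_umis <= 0) stop("median_cell_umis: must be positive")

  k <- length(cell_types)
  if (is.null(type_gradients)) {
    type_gradients <- matrix(1, k, length(gradient_anchors),
                             dimnames = list(cell_types, NULL))
    # defaults: neurons anterior-heavy, gut mid-body, parenchyma posterior
    if ("neuron" %in% cell_types)
      type_gradients["neuron", ] <- stats::approx(c(0, 0.5, 1), c(3, 1, 0.5),
                                                  gradient_anchors, rule = 2)$y
    if ("gut" %in% cell_types)
      type_gradients["gut", ] <- stats::approx(c(0, 0.5, 1), c(0.5, 2, 1),
                                               gradient_anchors, rule = 2)$y
    if ("parenchymal" %in% cell_types)
      type_gradients["parenchymal", ] <- stats::approx(c(0, 0.5, 1),
                                                       c(0.5, 1, 2.5),
                                                       gradient_anchors, rule = 2)$y
  }
  type_gradients <- as.matrix(type_gradients)
  if (nrow(type_gradients) != k || ncol(type_gradients) != length(gradient_anchors))
    stop("type_gradients: must be |cell_types| x |gradient_anchors|")
  if (any(type_gradients < 0)) stop("type_gradients: weights must be nonnegative")
  rownames(type_gradients) <- cell_types

  n_marker_block <- k * markers_per_type + n_domain_genes
  if (n_genes < n_marker_block + 4)
    stop("n_genes: too small for the requested markers and domain genes")

  if (is.null(lr_pairs)) {
    gid <- function(i) sprintf("g%04d", i)
    base <- n_marker_block
    lr_pairs <- data.frame(
      ligand = gid(base + c(1L, 3L)),
      receptor = gid(base + c(2L, 4L)),
      slope = c(0.8, 0.5),
      stringsAsFactors = FALSE
    )
  }

  cfg <- list(n_sections = as.integer(n_sections),
              section_spacing = section_spacing, spot_pitch = spot_pitch,
              body_length = body_length, body_width = body_width,
              body_shape = body_shape, cell_types = cell_types,
              type_gradients = type_gradients,
              gradient_anchors = gradient_anchors,
              neoblast_fraction = neoblast_fraction,
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              marker_fold_change = marker_fold_change,
              n_domain_genes = as.integer(n_domain_genes),
              domain_fold_change = domain_fold_change,
              median_spot_umis = median_spot_umis,
              median_cell_umis = median_cell_umis,
              n_cells = as.integer(n_cells), dispersion = dispersion,
              cells_per_spot = as.integer(cells_per_spot),
              lr_pairs = lr_pairs, lr_dispersion = lr_dispersion,
              doublet_rate = doublet_rate, lowq_rate = lowq_rate,
              seed = as.integer(seed))
  class(cfg) <- "worm_config"
  cfg
}

# spot grid clipped to the body outline, in the aligned (true) frame
worm_grid <- function(config) {
  p <- config$spot_pitch
  if (p > config$body_width)
    stop("no spots: spot_pitch exceeds body_width")
  gx <- seq(p / 2, config$body_length, by = p)
  gy <- seq(p / 2, config$body_width, by = p)
  gx <- gx[gx <= config$body_length]
  gy <- gy[gy <= config$body_width]
  g <- expand.grid(x = gx, y = gy)
  if (config$body_shape == "ellipse") {
    a <- config$body_length / 2
    b <- config$body_width / 2
    keep <- ((g$x - a) / a)^2 + ((g$y - b) / b)^2 <= 1
    g <- g[keep, , drop = FALSE]
  }
  if (nrow(g) == 0) stop("no spots: grid is empty for this geometry")
  g <- g[order(g$x, g$y), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# composition (renormalized gradient weights) at arbitrary axis positions,
# using the neoblast calibration factor stored on the truth object
worm_composition_at <- function(config, axis_pos, neoblast_scale = 1) {
  w <- interp_weights(config$type_gradients, config$gradient_anchors, axis_pos)
  colnames(w) <- config$cell_types
  if ("neoblast" %in% config$cell_types)
    w[, "neoblast"] <- w[, "neoblast"] * neoblast_scale
  w / rowSums(w)
}

#' Generate a virtual worm with known ground truth
#'
#' Lays out a spot grid over an elliptical body per section, assigns each
#' spot a cell-type composition following the configured anterior-posterior
#' gradients (with the neoblast column calibrated to the target whole-worm
#' fraction), plants marker genes and domain genes into the type
#' signatures, samples single-cell labels, and draws per-section rigid
#' transforms recorded for alignment-recovery tests.
#'
#' @param config a [worm_config()] object.
#' @return a list of class `worm_truth` with elements `config`, `spots`,
#'   `spot_composition`, `domain_map`, `domain_genes`, `signatures`,
#'   `markers`, `cell_labels`, `cell_flags`, `planted_lr`,
#'   `transform_truth`, and `neoblast_scale`.
#' @export
make_worm <- function(config) {
  stopifnot(inherits(config, "worm_config"))
  with_seed(config$seed, {
    grid <- worm_grid(config)
    n_sec <- config$n_sections
    spots <- do.call(rbind, lapply(seq_len(n_sec) - 1L, function(s) {
      data.frame(section = s, x = grid$x, y = grid$y,
                 z = s * config$section_spacing,
                 array_row = as.integer(round(grid$y / config$spot_pitch + 0.5)),
                 array_col = as.integer(round(grid$x / config$spot_pitch + 0.5)))
    }))
    spots$spot_id <- sprintf("s%d_%04d", spots$section,
                             ave(spots$x, spots$section, FUN = seq_along))
    spots$axis_pos <- spots$x / config$body_length
    spots <- spots[, c("spot_id", "section", "array_row", "array_col",
                       "x", "y", "z", "axis_pos")]

    # calibrate the neoblast column mean to the target fraction
    neo_scale <- 1
    if ("neoblast" %in% config$cell_types && length(config$cell_types) > 1) {
      f <- function(g) {
        mean(worm_composition_at(config, spots$axis_pos, g)[, "neoblast"]) -
          config$neoblast_fraction
      }
      neo_scale <- stats::uniroot(f, c(1e-9, 1e9), tol = 1e-12)$root
    }
    comp <- worm_composition_at(config, spots$axis_pos, neo_scale)
    rownames(comp) <- spots$spot_id

    # planted spatial domain: a central disc (pharynx-like), per section
    cx <- config$body_length / 2
    cy <- config$body_width / 2
    r <- config$body_width / 4
    domain_map <- as.integer((spots$x - cx)^2 + (spots$y - cy)^2 <= r^2)

    # signatures: shared lognormal baseline, markers boosted in own type
    k <- length(config$cell_types)
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    base <- exp(rnorm(config$n_genes, 0, 0.5))
    sig <- matrix(rep(base, each = k), k, config$n_genes,
                  dimnames = list(config$cell_types, gene_ids))
    markers <- data.frame(gene = character(0), type = character(0))
    for (i in seq_len(k)) {
      idx <- (i - 1L) * config$markers_per_type + seq_len(config$markers_per_type)
      sig[i, idx] <- sig[i, idx] * config$marker_fold_change
      markers <- rbind(markers, data.frame(gene = gene_ids[idx],
                                           type = config$cell_types[i]))
    }
    domain_genes <- gene_ids[k * config$markers_per_type +
                               seq_len(config$n_domain_genes)]

    # single cells: labels from the whole-worm composition; flags planted
    probs <- colMeans(comp)
    cell_labels <- sample(config$cell_types, config$n_cells, TRUE, probs)
    n <- config$n_cells
    flags <- data.frame(doublet = runif(n) < config$doublet_rate,
                        lowq = FALSE)
    flags$lowq[!flags$doublet] <-
      runif(sum(!flags$doublet)) < config$lowq_rate / max(1e-12, 1 - config$doublet_rate)
    # second label for doublets
    partner <- sample(config$cell_types, n, TRUE, probs)
    flags$doublet_partner <- ifelse(flags$doublet, partner, NA_character_)

    # per-section rigid transforms (section 0 is the reference frame)
    theta <- c(0, runif(n_sec - 1, -15, 15) * pi / 180)
    tx <- c(0, runif(n_sec - 1, -20, 20))
    ty <- c(0, runif(n_sec - 1, -20, 20))
    transform_truth <- data.frame(section = seq_len(n_sec) - 1L,
                                  theta = theta, tx = tx, ty = ty)

    lr <- config$lr_pairs
    if (nrow(lr) > 0 && !all(c(lr$ligand, lr$receptor) %in% gene_ids))
      stop("lr_pairs: genes outside the expression universe")

    out <- list(config = config, spots = spots, spot_composition = comp,
                domain_map = domain_map, domain_genes = domain_genes,
                signatures = sig, markers = markers,
                cell_labels = cell_labels, cell_flags = flags,
                planted_lr = lr, transform_truth = transform_truth,
                neoblast_scale = neo_scale)
    class(out) <- "worm_truth"
    out
  })
}

rigid_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Emit the spot coordinate table
#'
#' @param truth a `worm_truth` from [make_worm()].
#' @param frame "aligned" returns the true common frame; "raw" applies each
#'   section's recorded rigid transform, emulating unaligned section images.
#' @return a data.frame with columns spot_id, section, array_row, array_col,
#'   x, y, z (micrometres) and axis_pos.
#' @export
sample_spots <- function(truth, frame = c("aligned", "raw")) {
  stopifnot(inherits(truth, "worm_truth"))
  frame <- match.arg(frame)
  spots <- truth$spots
  if (frame == "raw") {
    for (s in truth$transform_truth$section) {
      tr <- truth$transform_truth[truth$transform_truth$section == s, ]
      i <- spots$section == s
      xy <- as.matrix(spots[i, c("x", "y")]) %*% t(rigid_matrix(tr$theta))
      spots$x[i] <- xy[, 1] + tr$tx
      spots$y[i] <- xy[, 2] + tr$ty
    }
  }
  spots
}

#' Simulate UMI count matrices for spots or single cells
#'
#' Spot profiles are composition-weighted mixtures of the type signatures
#' (domain genes boosted inside the planted domain); single cells follow
#' their type's signature, with planted doublets (two-type mixtures at
#' elevated depth) and low-complexity cells (depth scaled down 25x).
#' Counts are negative binomial around the expected profile with the
#' configured dispersion (Poisson when `dispersion = Inf`). Library sizes
#' are lognormal, rescaled so the realized median matches the configured
#' target. For each planted ligand-receptor pair, the receptor column of
#' the spot matrix is regenerated as NB(exp(a + slope * lignorm)) where
#' lignorm is the log-normalized ligand expression, so the planted slope is
#' recoverable by [colocalization_degree()].
#'
#' @param truth a `worm_truth`.
#' @param who "spots" or "cells".
#' @param seed optional override of the stage seed derived from the config.
#' @return a list with `counts` (sparse dgCMatrix, units x genes) and
#'   `meta` (data.frame; for cells: true_type, doublet, lowq, doublet_score;
#'   for spots: the spot table row plus realized depth).
#' @export
simulate_counts <- function(truth, who = c("spots", "cells"), seed = NULL) {
  stopifnot(inherits(truth, "worm_truth"))
  who <- match.arg(who)
  cfg <- truth$config
  if (cfg$median_spot_umis <= 0 || cfg$median_cell_umis <= 0)
    stop("median UMI target must be positive")
  seed <- seed %||% stage_seed(cfg$seed, if (who == "spots") "simulate_spots"
                               else "simulate_cells")
  with_seed(seed, {
    gene_ids <- colnames(truth$signatures)
    rdraw <- function(mu, size) {
      if (is.infinite(size)) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = size)
    }
    if (who == "spots") {
      P <- truth$spot_composition %*% truth$signatures
      boost <- truth$domain_map == 1L
      P[boost, truth$domain_genes] <- P[boost, truth$domain_genes] *
        cfg$domain_fold_change
      P <- P / rowSums(P)
      n <- nrow(P)
      lib <- exp(rnorm(n, 0, 0.25)) * cfg$median_spot_umis
      lib <- lib * cfg$median_spot_umis / median(lib)
      mu <- P * lib
      counts <- matrix(rdraw(mu, cfg$dispersion * cfg$cells_per_spot), n,
                       ncol(P))
      dimnames(counts) <- list(truth$spots$spot_id, gene_ids)
      # plant ligand-receptor colocalization on the spot matrix
      if (nrow(truth$planted_lr) > 0) {
        tot <- rowSums(counts)
        for (j in seq_len(nrow(truth$planted_lr))) {
          pr <- truth$planted_lr[j, ]
          x <- log1p(counts[, pr$ligand] / pmax(tot, 1) * 1e4)
          a <- log(cfg$median_spot_umis / cfg$n_genes) - pr$slope * mean(x)
          counts[, pr$receptor] <- rnbinom(n, mu = exp(a + pr$slope * x),
                                           size = cfg$lr_dispersion)
        }
      }
      meta <- truth$spots
      meta$depth <- rowSums(counts)
      meta$domain <- truth$domain_map
    } else {
      sig <- truth$signatures / rowSums(truth$signatures)
      n <- cfg$n_cells
      P <- sig[truth$cell_labels, , drop = FALSE]
      dbl <- truth$cell_flags$doublet
      if (any(dbl)) {
        P[dbl, ] <- 0.5 * (sig[truth$cell_labels[dbl], , drop = FALSE] +
                           sig[truth$cell_flags$doublet_partner[dbl], , drop = FALSE])
      }
      lib <- exp(rnorm(n, 0, 0.25)) * cfg$median_cell_umis
      lib <- lib * cfg$median_cell_umis / median(lib)
      lib[dbl] <- lib[dbl] * 1.8
      lib[truth$cell_flags$lowq] <- lib[truth$cell_flags$lowq] * 0.04
      mu <- P * lib
      counts <- matrix(rdraw(mu, cfg$dispersion), n, ncol(P))
      dimnames(counts) <- list(sprintf("c%05d", seq_len(n)), gene_ids)
      meta <- data.frame(cell_id = rownames(counts),
                         true_type = truth$cell_labels,
                         doublet = dbl, lowq = truth$cell_flags$lowq,
                         doublet_score = as.numeric(dbl))
    }
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         meta = meta)
  })
}

#' Render synthetic histology patches for spots or arbitrary coordinates
#'
#' Stand-in for H&E crops: each patch encodes its class (the argmax
#' cell-type composition at its location) as a class-specific mean
#' intensity plus a class-frequency sinusoidal texture, corrupted by a
#' per-patch intensity offset and per-pixel Gaussian noise, both with
#' standard deviation (class spacing)/snr. High snr makes classes
#' separable by mean intensity; snr near zero reduces the best achievable
#' accuracy to chance.
#'
#' @param truth a `worm_truth`.
#' @param patch_px patch side in pixels (>= 8).
#' @param snr signal-to-noise ratio (> 0).
#' @param seed optional seed override.
#' @param coords optional data.frame(section, x, y) of target locations;
#'   default is every spot. Compositions at non-spot coordinates come from
#'   the underlying gradient field.
#' @return a list of class `patch_set`: `patches` (n x px x px array),
#'   `labels` (character), `coords`, `snr`.
#' @export
render_patches <- function(truth, patch_px = 60L, snr = 5, seed = NULL,
                           coords = NULL) {
  stopifnot(inherits(truth, "worm_truth"))
  if (patch_px < 8) stop("patch_px: must be >= 8")
  if (snr <= 0) stop("snr: must be positive")
  cfg <- truth$config
  seed <- seed %||% stage_seed(cfg$seed, "patches")
  if (is.null(coords)) {
    coords <- truth$spots[, c("section", "x", "y")]
    comp <- truth$spot_composition
  } else {
    comp <- worm_composition_at(cfg, coords$x / cfg$body_length,
                                truth$neoblast_scale)
  }
  labels <- cfg$cell_types[max.col(comp, ties.method = "first")]
  with_seed(seed, {
    k <- length(cfg$cell_types)
    delta <- 1 / (k + 1)
    n <- nrow(coords)
    px <- as.integer(patch_px)
    cls <- match(labels, cfg$cell_types)
    patches <- array(0, c(n, px, px))
    colphase <- 2 * pi * seq_len(px) / px
    sdn <- delta / snr
    offs <- rnorm(n, 0, sdn)
    for (i in seq_len(n)) {
      tex <- 0.5 * delta * sin(cls[i] * colphase)
      patches[i, , ] <- cls[i] * delta + offs[i] +
        matrix(tex, px, px, byrow = TRUE) +
        matrix(rnorm(px * px, 0, sdn), px, px)
    }
    out <- list(patches = patches, labels = labels,
                coords = cbind(coords, label = labels), snr = snr,
                types = cfg$cell_types)
    class(out) <- "patch_set"
    out
  })
}
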