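# Geometry engine: rigid section alignment, 3D spatial neighbor network,
# non-overlapping spot tiling, anterior-posterior axis segmentation.

#' Estimate a 2D rigid transform from landmark pairs
#'
#' Closed-form least-squares rotation + translation (orthogonal Procrustes
#' restricted to proper rotations) mapping `landmarks_a` onto
#' `landmarks_b`, as used to superimpose serial sections on characteristic
#' histology features.
#'
#' @param landmarks_a,landmarks_b n x 2 matrices of paired landmarks (n >= 2).
#' @return list of class `rigid_transform`: `theta` (radians), `tx`, `ty`,
#'   `rms` residual.
#' @export
estimate_rigid <- function(landmarks_a, landmarks_b) {
  A <- as.matrix(landmarks_a); B <- as.matrix(landmarks_b)
  if (nrow(A) < 2 || nrow(A) != nrow(B))
    stop("underdetermined: need >= 2 landmark pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (all(abs(A0) < 1e-12) || all(abs(B0) < 1e-12))
    stop("underdetermined: landmarks are coincident")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  D <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1])
  tvec <- cb - as.vector(R %*% ca)
  resid <- B - (A %*% t(R) + matrix(tvec, nrow(A), 2, byrow = TRUE))
  out <- list(theta = theta, tx = tvec[1], ty = tvec[2],
              rms = sqrt(mean(resid^2)))
  class(out) <- "rigid_transform"
  out
}

#' Apply, invert, or compose rigid transforms
#'
#' @param spots a spot table (columns x, y) or an n x 2 matrix.
#' @param transform a `rigid_transform`.
#' @return `apply_rigid`: the input with transformed x, y;
#'   `invert_rigid`/`compose_rigid`: a `rigid_transform`.
#' @export
apply_rigid <- function(spots, transform) {
  R <- rigid_matrix(transform$theta)
  if (is.matrix(spots)) {
    out <- spots %*% t(R)
    out[, 1] <- out[, 1] + transform$tx
    out[, 2] <- out[, 2] + transform$ty
    return(out)
  }
  xy <- as.matrix(spots[, c("x", "y")]) %*% t(R)
  spots$x <- xy[, 1] + transform$tx
  spots$y <- xy[, 2] + transform$ty
  spots
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  R <- rigid_matrix(-transform$theta)
  tv <- -as.vector(R %*% c(transform$tx, transform$ty))
  out <- list(theta = -transform$theta, tx = tv[1], ty = tv[2], rms = NA_real_)
  class(out) <- "rigid_transform"
  out
}

#' @rdname apply_rigid
#' @param first,second transforms; the result applies `first` then `second`.
#' @export
compose_rigid <- function(first, second) {
  R2 <- rigid_matrix(second$theta)
  tv <- as.vector(R2 %*% c(first$tx, first$ty)) + c(second$tx, second$ty)
  out <- list(theta = first$theta + second$theta, tx = tv[1], ty = tv[2],
              rms = NA_real_)
  class(out) <- "rigid_transform"
  out
}

#' Align raw sections back to a reference frame
#'
#' Estimates one rigid transform per section from landmark pairs (shared
#' spot positions by default) and applies its inverse, undoing per-section
#' placement.
#'
#' @param spots a spot table in the raw frame.
#' @param reference the spot table in the reference frame (same spot_ids).
#' @return list: `spots` (aligned table), `transforms` (per section, the
#'   estimated reference->raw transform).
#' @export
align_sections <- function(spots, reference) {
  secs <- sort(unique(spots$section))
  out <- spots
  trs <- list()
  for (s in secs) {
    i <- spots$section == s
    m <- match(spots$spot_id[i], reference$spot_id)
    tr <- estimate_rigid(as.matrix(reference[m, c("x", "y")]),
                         as.matrix(spots[i, c("x", "y")]))
    out[i, c("x", "y")] <- apply_rigid(as.matrix(spots[i, c("x", "y")]),
                                       invert_rigid(tr))
    trs[[as.character(s)]] <- tr
  }
  list(spots = out, transforms = trs)
}

#' Build the 3D spatial neighbor network
#'
#' Links spots of the same section at in-plane distance strictly below
#' `within_thresh`, and spots of adjacent sections (|section difference|
#' = 1) at in-plane distance strictly below `between_thresh`. Distances
#' are Euclidean in the aligned x-y plane; coordinates must share a unit.
#'
#' @param spots aligned spot table (spot_id, section, x, y).
#' @param within_thresh,between_thresh distance thresholds (defaults 150
#'   and 100, in the coordinate unit of the table).
#' @return data.frame edge list (from, to, distance, class) with class in
#'   {within_section, between_section}; each undirected edge appears once.
#' @export
build_3d_graph <- function(spots, within_thresh = 150, between_thresh = 100) {
  stopifnot(all(c("spot_id", "section", "x", "y") %in% names(spots)))
  edges <- list()
  secs <- sort(unique(spots$section))
  for (s in secs) {
    a <- spots[spots$section == s, ]
    if (nrow(a) > 1) {
      d <- as.matrix(stats::dist(a[, c("x", "y")]))
      idx <- which(upper.tri(d) & d < within_thresh, arr.ind = TRUE)
      if (nrow(idx)) {
        edges[[length(edges) + 1]] <- data.frame(
          from = a$spot_id[idx[, 1]], to = a$spot_id[idx[, 2]],
          distance = d[idx], class = "within_section")
      }
    }
    if ((s + 1) %in% secs) {
      b <- spots[spots$section == s + 1, ]
      cd <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
      idx <- which(cd < between_thresh^2, arr.ind = TRUE)
      if (nrow(idx)) {
        edges[[length(edges) + 1]] <- data.frame(
          from = a$spot_id[idx[, 1]], to = b$spot_id[idx[, 2]],
          distance = sqrt(cd[idx]), class = "between_section")
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(from = character(0), to = character(0),
                      distance = numeric(0), class = character(0)))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Tile spots from consecutive sections onto a base array
#'
#' The base array is the base section's spots plus half-pitch imputed
#' midpoints (see [impute_midpoints()]). Every input spot, from every
#' section, is assigned to its single nearest base node (ties broken by
#' lower node index, deterministic); node scores are the sums of their
#' assigned spots' score vectors, so total score mass is conserved.
#'
#' @param spots aligned spot table across sections.
#' @param scores matrix (rows = spots, any columns) of per-spot scores.
#' @param base_section section index supplying the base array.
#' @param pitch grid pitch used for midpoint imputation; NULL to tile onto
#'   the raw base spots only.
#' @return list: `nodes` (data.frame x, y plus accumulated scores),
#'   `assignment` (base node index per input spot), `n_contrib` per node.
#' @export
tile_spots <- function(spots, scores, base_section, pitch = NULL) {
  base <- spots[spots$section == base_section, ]
  if (nrow(base) == 0) stop("empty base section")
  nodes <- base[, c("x", "y")]
  if (!is.null(pitch)) {
    mids <- impute_midpoints(base, pitch)
    nodes <- rbind(nodes, mids[, c("x", "y")])
  }
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(spots)) stop("scores must have one row per spot")
  d2 <- outer(spots$x, nodes$x, "-")^2 + outer(spots$y, nodes$y, "-")^2
  assign_idx <- apply(d2, 1, which.min)   # which.min takes the lowest index on ties
  acc <- matrix(0, nrow(nodes), ncol(scores),
                dimnames = list(NULL, colnames(scores)))
  n_contrib <- integer(nrow(nodes))
  agg <- rowsum(scores, assign_idx)
  acc[as.integer(rownames(agg)), ] <- agg
  tabs <- table(assign_idx)
  n_contrib[as.integer(names(tabs))] <- as.integer(tabs)
  list(nodes = cbind(nodes, acc), assignment = assign_idx,
       n_contrib = n_contrib)
}

#' Segment spots along the anterior-posterior axis
#'
#' Projects aligned spots on the body axis (the first principal axis of
#' the x-y coordinates unless an explicit axis is given), oriented so the
#' supplied anterior landmark has the smallest projection, and cuts the
#' projection range into `n_segments` equal-width bins; segment 1 is
#' anterior and the last bin is right-closed.
#'
#' @param spots aligned spot table.
#' @param n_segments number of segments (10 for intact worms, 7 for
#'   regenerating time points; must be >= 2).
#' @param anterior length-2 coordinate of an anterior landmark (used only
#'   to orient the axis).
#' @param axis optional explicit unit vector; NULL uses PCA.
#' @return list of class `segment_partition`: `segment` (integer 1..n per
#'   spot), `axis` (unit vector), `origin`, `breaks`.
#' @export
segment_ap_axis <- function(spots, n_segments, anterior = c(0, 0),
                            axis = NULL) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  xy <- as.matrix(spots[, c("x", "y")])
  if (is.null(axis)) {
    axis <- prcomp(xy, rank. = 1)$rotation[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  origin <- colMeans(xy)
  proj <- as.vector((xy - matrix(origin, nrow(xy), 2, byrow = TRUE)) %*% axis)
  pa <- sum((as.numeric(anterior) - origin) * axis)
  if (pa > mean(range(proj))) {   # flip so anterior projects low
    axis <- -axis
    proj <- -proj
  }
  if (length(unique(proj)) < n_segments)
    stop("fewer distinct axis positions than segments")
  breaks <- seq(min(proj), max(proj), length.out = n_segments + 1)
  seg <- findInterval(proj, breaks, rightmost.closed = TRUE)
  seg[seg < 1] <- 1L; seg[seg > n_segments] <- n_segments
  out <- list(segment = as.integer(seg), axis = axis, origin = origin,
              breaks = breaks, n_segments = as.integer(n_segments))
  class(out) <- "segment_partition"
  out
}
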