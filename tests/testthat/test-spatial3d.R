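test_that("rigid transforms rotate, invert and compose exactly", {
  tr <- structure(list(theta = pi / 2, tx = 0, ty = 0),
                  class = "rigid_transform")
  expect_equal(as.numeric(apply_rigid(matrix(c(1, 0), 1), tr)), c(0, 1))
  set.seed(1)
  A <- matrix(runif(6, 0, 10), 3, 2)
  truth <- structure(list(theta = -0.7, tx = 12, ty = -3),
                     class = "rigid_transform")
  B <- apply_rigid(A, truth)
  est <- estimate_rigid(A, B)
  expect_lt(abs(est$theta - truth$theta), 1e-9)
  expect_lt(abs(est$tx - truth$tx), 1e-9)
  expect_lt(abs(est$ty - truth$ty), 1e-9)
  expect_lt(est$rms, 1e-9)
  ident <- compose_rigid(est, invert_rigid(est))
  expect_lt(abs(ident$theta), 1e-9)
  expect_lt(abs(ident$tx) + abs(ident$ty), 1e-9)
  expect_error(estimate_rigid(A[1, , drop = FALSE], B[1, , drop = FALSE]),
               "underdetermined")
  same <- matrix(1, 4, 2)
  expect_error(estimate_rigid(same, same), "underdetermined")
})

test_that("generator section placements are recovered exactly from noiseless spots", {
  tr <- small_worm(seed = 8)
  raw <- sample_spots(tr, "raw")
  ref <- sample_spots(tr, "aligned")
  al <- align_sections(raw, ref)
  for (s in tr$transform_truth$section) {
    est <- al$transforms[[as.character(s)]]
    tt <- tr$transform_truth[tr$transform_truth$section == s, ]
    expect_lt(abs(est$theta - tt$theta), 1e-9)
    expect_lt(abs(est$tx - tt$tx), 1e-9)
    expect_lt(abs(est$ty - tt$ty), 1e-9)
  }
  expect_equal(al$spots$x, ref$x, tolerance = 1e-9)
})

test_that("the 3D graph applies strict thresholds to the right section pairs", {
  sp <- data.frame(spot_id = c("a", "b", "c", "d", "e", "f"),
                   section = c(0, 0, 0, 1, 1, 2),
                   x = c(0, 100, 300, 50, 0, 0),
                   y = c(0, 0, 0, 0, 120, 0))
  e <- build_3d_graph(sp)
  key <- paste(e$from, e$to)
  expect_true("a b" %in% key)        # same section, d = 100 < 150
  expect_false("a c" %in% key)       # same section, d = 300
  expect_false("b c" %in% key)       # same section, d = 200
  expect_true("a d" %in% key)        # adjacent, d = 50 < 100
  expect_false("a e" %in% key)       # adjacent, d = 120
  expect_false("a f" %in% key)       # sections 0 and 2, d = 0
  expect_true(all(e$class[e$from == "a" & e$to == "d"] == "between_section"))
  # boundary is strict
  sp2 <- data.frame(spot_id = c("p", "q", "r"), section = c(0, 0, 1),
                    x = c(0, 150, 100), y = 0)
  e2 <- build_3d_graph(sp2)
  # p-q sits exactly at 150 (within) and p-r exactly at 100 (between):
  # both excluded by strictness; only q-r (d = 50, adjacent) remains
  expect_equal(nrow(e2), 1)
  expect_equal(paste(e2$from, e2$to), "q r")
})

test_that("the 3D graph matches an all-pairs brute-force oracle", {
  set.seed(7)
  n <- 300
  sp <- data.frame(spot_id = sprintf("s%03d", 1:n),
                   section = sample(0:2, n, TRUE),
                   x = runif(n, 0, 600), y = runif(n, 0, 600))
  e <- build_3d_graph(sp)
  got <- sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((sp$x[i] - sp$x[j])^2 + (sp$y[i] - sp$y[j])^2)
    ds <- abs(sp$section[i] - sp$section[j])
    if ((ds == 0 && d < 150) || (ds == 1 && d < 100)) {
      want <- c(want, paste(pmin(sp$spot_id[i], sp$spot_id[j]),
                            pmax(sp$spot_id[i], sp$spot_id[j])))
    }
  }
  expect_identical(got, sort(want))
  # invariant under a global rigid motion of all sections jointly
  tr <- structure(list(theta = 0.3, tx = 40, ty = -5),
                  class = "rigid_transform")
  sp3 <- apply_rigid(sp, tr)
  e3 <- build_3d_graph(sp3)
  expect_identical(sort(paste(pmin(e3$from, e3$to), pmax(e3$from, e3$to))),
                   got)
})

test_that("tiling conserves score mass and assigns each spot once", {
  # two identical sections of 4 spots, unit scores
  base <- data.frame(spot_id = sprintf("a%d", 1:4), section = 0,
                     x = c(0, 10, 0, 10), y = c(0, 0, 10, 10))
  top <- transform(base, spot_id = sprintf("b%d", 1:4), section = 1)
  spots <- rbind(base, top)
  til <- tile_spots(spots, matrix(1, 8, 1), base_section = 0)
  expect_equal(sort(til$nodes[, 3], decreasing = TRUE), c(2, 2, 2, 2))
  expect_equal(sum(til$nodes[, 3]), 8)      # mass conserved
  expect_equal(length(til$assignment), 8)   # every spot assigned exactly once
  # a single section tiles onto itself
  one <- tile_spots(base, matrix(5, 4, 1), base_section = 0)
  expect_equal(unname(one$nodes[, 3]), rep(5, 4))
  # exact midway tie goes to the lower node index
  spots2 <- rbind(base, data.frame(spot_id = "m", section = 1, x = 5, y = 0))
  t2 <- tile_spots(spots2, matrix(1, 5, 1), base_section = 0)
  expect_equal(t2$assignment[5], 1)
  expect_error(tile_spots(spots, matrix(1, 8, 1), base_section = 9), "empty base")
  # with midpoints the node array grows but mass is still conserved
  t3 <- tile_spots(spots, matrix(1, 8, 1), base_section = 0, pitch = 10)
  expect_gt(nrow(t3$nodes), 4)
  expect_equal(sum(t3$nodes[, 3]), 8)
})

test_that("A-P segmentation bins projections into equal widths", {
  set.seed(2)
  sp <- data.frame(spot_id = sprintf("s%d", 1:101),
                   x = seq(0, 100, by = 1), y = rnorm(101, 0, 0.01))
  seg <- segment_ap_axis(sp, 10, anterior = c(0, 0))
  expect_equal(seg$segment[sp$x == 5], 1)
  expect_equal(seg$segment[sp$x == 99], 10)
  expect_equal(length(seg$segment), 101)
  expect_equal(sum(table(seg$segment)), 101)
  # orientation follows the anterior landmark
  seg_flip <- segment_ap_axis(sp, 10, anterior = c(100, 0))
  expect_equal(seg_flip$segment[sp$x == 99], 1)
  expect_error(segment_ap_axis(sp, 1), "n_segments")
})
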