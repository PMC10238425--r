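test_that("deconvolution recovers pure spots, simple mixtures and orthogonal designs", {
  tr <- small_worm(seed = 2)
  sig <- tr$signatures
  # a pure-type profile maps to the one-hot row scaled to 30 cells
  pure <- sig["gut", , drop = FALSE] * 50
  rownames(pure) <- "spot1"
  ab <- estimate_abundance(pure, sig)
  expect_equal(unname(ab$abundance[1, "gut"]), 30, tolerance = 1e-8)
  expect_equal(sum(ab$abundance), 30, tolerance = 1e-8)
  # 0.7/0.3 near-noiseless mixture
  mix <- 0.7 * sig["neuron", ] / sum(sig["neuron", ]) +
         0.3 * sig["muscle", ] / sum(sig["muscle", ])
  m <- matrix(round(mix * 2e6), 1, dimnames = list("m1", colnames(sig)))
  abm <- estimate_abundance(m, sig)
  expect_lt(abs(abm$proportions[1, "neuron"] - 0.7), 0.05)
  expect_lt(abs(abm$proportions[1, "muscle"] - 0.3), 0.05)
  # orthogonal two-gene signatures: counts (70, 30) -> coefficients 70:30
  s2 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("A", "B"), c("gX", "gY")))
  y2 <- matrix(c(70, 30), 1, 2, dimnames = list("s", c("gX", "gY")))
  ab2 <- estimate_abundance(y2, s2)
  expect_equal(unname(ab2$proportions[1, ]), c(0.7, 0.3), tolerance = 1e-6)
  # identical signatures trigger the merged-type warning
  s3 <- rbind(s2, C = s2["A", ])
  expect_warning(estimate_abundance(y2, s3), "near-identical")
})

test_that("deconvolution RMSE stays within 0.05 on generator spots", {
  tr <- small_worm(seed = 3)
  sc <- simulate_counts(tr, "spots")
  ab <- estimate_abundance(sc$counts, tr$signatures)
  expect_lt(sqrt(mean((ab$proportions - tr$spot_composition)^2)), 0.05)
})

test_that("top-k co-occurrence counts the right pairs", {
  m <- matrix(c(.5, .3, .15, .05), 1,
              dimnames = list("s1", c("A", "B", "C", "D")))
  co <- top_k_cooccurrence(m, 3)
  expect_equal(co["A", "B"], 1L)
  expect_equal(co["A", "C"], 1L)
  expect_equal(co["B", "C"], 1L)
  expect_equal(sum(co), 6L)            # 3 pairs, symmetric
  expect_equal(unname(diag(co)), rep(0L, 4))
  expect_true(isSymmetric(co))
  # k = 1 has no pairs; duplicated spots double every count
  expect_equal(sum(top_k_cooccurrence(m, 1)), 0L)
  co2 <- top_k_cooccurrence(rbind(m, m), 3)
  expect_equal(unname(co2["A", "B"]), 2L)
  # total = n_spots * choose(k, 2) when every spot has >= k nonzero types
  set.seed(1)
  mm <- matrix(runif(40, 0.1, 1), 10, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  expect_equal(sum(top_k_cooccurrence(mm, 3)) / 2, 10 * choose(3, 2))
  expect_error(top_k_cooccurrence(m, 5), "k exceeds")
})

test_that("class balancing caps classes deterministically", {
  tr <- banded_worm(n_sections = 1)
  ps <- render_patches(tr, patch_px = 12, snr = 5)
  sizes <- table(ps$labels)
  cap <- min(sizes) + 2
  bal <- balance_training(ps, cap, seed = 4)
  expect_equal(unname(table(bal$labels)), unname(pmin(sizes, cap)),
               ignore_attr = TRUE)
  expect_identical(balance_training(ps, cap, seed = 4)$labels, bal$labels)
  big <- balance_training(ps, 1e6, seed = 4)
  expect_equal(length(big$labels), length(ps$labels))
})

test_that("the patch classifier separates high-snr classes and is calibrated", {
  tr <- banded_worm(n_sections = 1)
  ps <- render_patches(tr, patch_px = 20, snr = 50)
  clf <- train_patch_classifier(ps, folds = 5, seed = 1)
  expect_gte(clf$cv_accuracy, 0.99)
  expect_equal(nrow(clf$cv), 5)
  p <- predict(clf, ps)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  # stratification error when a class cannot fill the folds
  few <- subset_idx <- c(which(ps$labels == ps$labels[1])[1:3],
                         which(ps$labels != ps$labels[1]))
  ps_few <- planastra:::subset_patches(ps, few)
  expect_error(train_patch_classifier(ps_few, folds = 5), "stratification")
})

test_that("midpoint imputation enlarges a grid with the documented edge rule", {
  grid <- data.frame(section = 0, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  mids <- impute_midpoints(grid, pitch = 1)
  expect_equal(nrow(mids), 8)   # 4 horizontal + 4 vertical
  expect_true(all(mids$x %% 0.5 == 0))
  # midpoints plus one imputed section at least double the spot count
  expect_gte((nrow(grid) + nrow(mids) + nrow(grid)) / (2 * nrow(grid)), 2)
})

test_that("pseudo-label transfer labels a new section near CV accuracy", {
  tr <- banded_worm(n_sections = 2)
  sec0 <- tr$spots$section == 0
  ps <- render_patches(tr, patch_px = 20, snr = 8)
  train <- planastra:::subset_patches(ps, which(sec0))
  target <- planastra:::subset_patches(ps, which(!sec0))
  clf <- train_patch_classifier(train, folds = 5, seed = 2)
  # plain prediction leaves the training set untouched
  plain <- impute_unsequenced(clf, target, target = "new_section",
                              pseudo_label_rounds = 0)
  expect_equal(nrow(attr(plain, "classifier")$features), nrow(clf$features))
  acc0 <- mean(plain$label == target$labels)
  se <- sqrt(clf$cv_accuracy * (1 - clf$cv_accuracy) / length(target$labels))
  expect_gte(acc0, clf$cv_accuracy - 3 * se - 0.02)
  # one pseudo-label round must not reduce accuracy materially
  pl <- impute_unsequenced(clf, target, target = "new_section",
                           pseudo_label_rounds = 1)
  acc1 <- mean(pl$label == target$labels)
  expect_gte(acc1, acc0 - 3 * se - 0.02)
  expect_true(all(pl$provenance == "imputed"))
  expect_error(impute_unsequenced(NULL, target, target = "new_section"),
               "adjacent")
})
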