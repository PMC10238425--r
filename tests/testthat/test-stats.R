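test_that("the hypergeometric tail matches a frozen big-integer oracle", {
  # expected values computed by exact rational arithmetic (30 decimal digits)
  oracle <- read.csv(test_path("hypergeom_exact.csv"),
                     colClasses = c(rep("integer", 4), "character"))
  for (i in seq_len(nrow(oracle))) {
    got <- hypergeom_tail(oracle$k[i], oracle$N[i], oracle$K[i], oracle$n[i])
    want <- as.numeric(oracle$p[i])
    expect_lt(abs(got - want), 1e-12 * max(want, 1e-300))
  }
})

test_that("the hypergeometric tail agrees with stats::phyper over all N <= 60", {
  worst <- 0
  for (N in 2:60) {
    for (K in seq(1, N, by = 3)) {
      for (n in seq(1, N, by = 3)) {
        for (k in 0:min(K, n)) {
          got <- hypergeom_tail(k, N, K, n)
          want <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
          worst <- max(worst, abs(got - want) / max(want, 1e-300))
        }
      }
    }
  }
  expect_lt(worst, 1e-11)
  expect_equal(hypergeom_tail(0, 50, 10, 20), 1)
  expect_equal(hypergeom_tail(20, 60, 60, 20), 1)   # K = N forces overlap
  expect_error(hypergeom_tail(6, 10, 5, 5), "exceeds")
})

test_that("anterior-enriched types are flagged only in anterior segments", {
  tr <- small_worm(seed = 4)
  sc <- simulate_counts(tr, "spots")
  norm <- normalize_log(sc$counts)
  seg <- segment_ap_axis(sample_spots(tr), 7, anterior = c(0, 150))
  mk <- rank_markers(norm, paste0("seg", seg$segment))
  keep <- mk$adjusted_p < 0.05 & mk$log_fold_change > 0
  seg_sets <- split(mk$gene[keep], mk$group[keep])
  type_sets <- split(tr$markers$gene, tr$markers$type)
  enr <- hypergeom_enrichment(type_sets, seg_sets, colnames(sc$counts))
  expect_true(all(enr$p >= 0 & enr$p <= 1))
  expect_identical(enr$mask, enr$p < 0.05)
  # neurons are planted anterior-high: enriched anteriorly, never posteriorly
  segs <- colnames(enr$p)
  first <- paste0("seg", 1); last <- paste0("seg", 7)
  if (first %in% segs) expect_lt(enr$p["neuron", first], 0.05)
  if (last %in% segs) expect_gte(enr$p["neuron", last], 0.05)
})

test_that("communication strength is the product of population means", {
  expr <- matrix(0, 6, 2, dimnames = list(sprintf("c%d", 1:6),
                                          c("lig", "rec")))
  lab <- rep(c("S", "R"), each = 3)
  expr[lab == "S", "lig"] <- 2
  expr[lab == "R", "rec"] <- 3
  db <- data.frame(ligand = "lig", receptor = "rec")
  res <- communication_strength(expr, lab, db, n_perm = 50, seed = 1)
  sc <- res$scores
  expect_equal(sc$score[sc$sender == "S" & sc$receiver == "R"], 6)
  # ligand absent from the sender: score 0 regardless of receptor
  expect_equal(sc$score[sc$sender == "R" & sc$receiver == "R"], 0)
  # bilinearity: doubling ligand expression doubles the score
  res2 <- communication_strength(expr * 2, lab, db, n_perm = 50, seed = 1)
  expect_equal(res2$scores$score, 4 * sc$score)
  expect_error(communication_strength(expr, lab,
                                      data.frame(ligand = "nope",
                                                 receptor = "rec")),
               "absent")
})

test_that("label shuffling destroys planted communication significance", {
  set.seed(11)
  n <- 120
  lab <- rep(c("S", "R"), each = n / 2)
  expr <- matrix(rexp(n * 4, 1), n, 4,
                 dimnames = list(NULL, c("ligA", "recA", "ligB", "recB")))
  expr[lab == "S", "ligA"] <- expr[lab == "S", "ligA"] + 4
  expr[lab == "R", "recA"] <- expr[lab == "R", "recA"] + 4
  db <- data.frame(ligand = c("ligA", "ligB"), receptor = c("recA", "recB"))
  res <- communication_strength(expr, lab, db, n_perm = 200, seed = 3)
  sc <- res$scores
  expect_lt(sc$p_value[sc$sender == "S" & sc$receiver == "R" &
                         sc$ligand == "ligA"], 0.05)
  # after destroying the labels, the planted pair is no longer significant
  null_sig <- replicate(20, {
    shuf <- sample(lab)
    r0 <- communication_strength(expr, shuf, db, n_perm = 99,
                                 seed = sample.int(1e6, 1))
    s0 <- r0$scores
    s0$p_value[s0$sender == "S" & s0$receiver == "R" & s0$ligand == "ligA"]
  })
  expect_gte(mean(null_sig > 0.05), 0.8)
})

test_that("NB colocalization recovers planted slopes", {
  set.seed(21)
  n <- 1000
  hits <- 0; reps <- 20
  for (r in seq_len(reps)) {
    lig <- rnbinom(n, mu = exp(rnorm(n, 3, 1)), size = 2)
    pad <- rpois(n, 20000)   # a large background library, as in real spots
    xcov <- log1p(lig / (lig + pad) * 1e4)
    y <- rnbinom(n, mu = exp(0.5 + 0.8 * xcov), size = 2)
    counts <- cbind(lig = lig, rec = y, pad = pad)
    rownames(counts) <- sprintf("s%d", 1:n)
    cr <- colocalization_degree(counts, "lig", "rec")
    hits <- hits + (abs(cr$slope - 0.8) <= 0.16)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("null pairs are rarely called and errors are informative", {
  set.seed(22)
  n <- 1000
  fp <- replicate(20, {
    counts <- cbind(lig = rnbinom(n, mu = 20, size = 2),
                    rec = rnbinom(n, mu = 10, size = 2),
                    pad = rpois(n, 20000))
    rownames(counts) <- sprintf("s%d", 1:n)
    cr <- colocalization_degree(counts, "lig", "rec")
    abs(cr$slope) > 3 * cr$se
  })
  expect_lte(mean(fp), 0.1)
  counts <- cbind(lig = rep(5, 50), rec = rpois(50, 5))
  rownames(counts) <- sprintf("s%d", 1:50)   # constant raw ligand counts
  expect_error(colocalization_degree(counts, "lig", "rec"), "constant")
  counts2 <- cbind(lig = rpois(50, 5), rec = 0)
  rownames(counts2) <- sprintf("s%d", 1:50)
  expect_error(colocalization_degree(counts2, "lig", "rec"), "zero")
  expect_error(colocalization_degree(counts[1:10, ], "lig", "rec"), "30")
})

test_that("Poisson-simulated data matches a Poisson-GLM oracle", {
  set.seed(23)
  n <- 800
  lig <- rpois(n, 30)
  pad <- rpois(n, 20000)
  y <- rpois(n, exp(0.2 + 0.6 * log1p(lig / (lig + pad) * 1e4)))
  counts <- cbind(lig = lig, rec = y, pad = pad)
  rownames(counts) <- sprintf("s%d", 1:n)
  suppressMessages(cr <- colocalization_degree(counts, "lig", "rec"))
  xfit2 <- log1p(lig / rowSums(counts) * 1e4)
  oracle <- glm(y ~ xfit2, family = poisson())
  # the NB fit approaches the Poisson solution as the dispersion diverges
  expect_lt(abs(cr$slope - unname(coef(oracle)[2])), 1e-3)
})

test_that("module scores contrast planted domains and ignore random sets", {
  tr <- small_worm(seed = 5)
  sc <- simulate_counts(tr, "spots")
  norm <- normalize_log(sc$counts)
  ms <- module_score(norm, tr$domain_genes, seed = 9)
  ins <- tr$domain_map == 1
  expect_gte((mean(ms[ins]) - mean(ms[!ins])) / sd(ms[!ins]), 5)
  # a random set centred by matched controls scores ~0
  set.seed(10)
  rnd <- sample(setdiff(colnames(norm), c(tr$markers$gene, tr$domain_genes)), 30)
  msr <- module_score(norm, rnd, seed = 9)
  expect_lt(abs(mean(msr)), 3 * sd(msr) / sqrt(length(msr)))
  expect_error(module_score(norm, character(0)), "empty")
  expect_error(module_score(norm, "not_a_gene"), "absent")
  expect_warning(module_score(norm, colnames(norm)[1:800], seed = 1),
                 "degenerate")
})

test_that("a module built from a type's markers correlates most with that type", {
  tr <- small_worm(seed = 6)
  sc <- simulate_counts(tr, "spots")
  norm <- normalize_log(sc$counts)
  ab <- estimate_abundance(sc$counts, tr$signatures)
  mods <- sapply(c("neuron", "gut"), function(tt)
    module_score(norm, tr$markers$gene[tr$markers$type == tt], seed = 2))
  cm <- module_celltype_correlation(mods, ab)
  expect_equal(colnames(cm)[which.max(cm["neuron", ])], "neuron")
  expect_equal(colnames(cm)[which.max(cm["gut", ])], "gut")
  expect_equal(dim(cm), c(2L, 7L))
})
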