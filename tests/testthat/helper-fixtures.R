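# Shared fixtures, all generated in code.

# Small worm for fast module tests (3 sections, ~300 spots, 7 types).
small_worm <- function(seed = 3, ...) {
  make_worm(worm_config(seed = seed, ...))
}

# A worm whose argmax cell type forms three balanced bands along the axis,
# for patch-classification tests (anterior neurons, mid gut, posterior
# parenchyma dominate in turn).
banded_worm <- function(seed = 5, ...) {
  grad <- rbind(neuron = c(6, 0.3, 0.1),
                gut = c(0.3, 6, 0.3),
                parenchymal = c(0.1, 0.3, 6))
  make_worm(worm_config(seed = seed,
                        cell_types = rownames(grad),
                        type_gradients = grad, ...))
}

# Disconnected dense blocks as an SNN-style adjacency. Each block is an ER
# graph dense enough that no modularity-improving split or merge exists at
# Louvain resolution 2 (within-degree^2 well below total edge count).
planted_block_graph <- function(n_per = 30, k = 3, p = 0.5, seed = 1) {
  n <- n_per * k
  a <- matrix(0, n, n)
  set.seed(seed)
  for (b in seq_len(k)) {
    idx <- (b - 1) * n_per + seq_len(n_per)
    blk <- matrix(runif(n_per^2) < p, n_per, n_per)
    blk[lower.tri(blk)] <- t(blk)[lower.tri(blk)]
    diag(blk) <- 0
    a[idx, idx] <- blk
  }
  rownames(a) <- colnames(a) <- sprintf("u%03d", seq_len(n))
  Matrix::Matrix(a, sparse = TRUE)
}

# Construct a counts matrix with prescribed per-cell nGene and nCount.
toy_counts <- function(nGene, nCount, n_genes = max(nGene) + 10) {
  n <- length(nGene)
  m <- matrix(0, n, n_genes,
              dimnames = list(sprintf("cell%d", seq_len(n)),
                              sprintf("g%d", seq_len(n_genes))))
  for (i in seq_len(n)) {
    m[i, seq_len(nGene[i])] <- 1
    m[i, 1] <- nCount[i] - nGene[i] + 1
  }
  Matrix::Matrix(m, sparse = TRUE)
}
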