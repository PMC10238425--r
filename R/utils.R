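# internal helpers shared across modules

#' @importFrom stats rnorm rnbinom rpois runif median quantile var sd cor
#'   prcomp p.adjust wilcox.test glm poisson predict coef pnorm setNames
#'   aggregate complete.cases
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic stages route through this so
# that one global seed plus fixed stage offsets determines every output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Stage-scoped substream: stable offset per stage name so changing one
# stage's draws cannot perturb another's.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate_spots = 101L, simulate_cells = 211L, patches = 307L,
               ensemble = 401L, rescue = 503L, balance = 601L,
               classifier = 701L, module = 809L, permutation = 907L,
               pipeline = 1009L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2000000000L) + off
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear interpolation of per-type anchor weights along the axis
interp_weights <- function(anchors, positions, t) {
  vapply(seq_len(nrow(anchors)), function(i) {
    stats::approx(positions, anchors[i, ], xout = t, rule = 2)$y
  }, numeric(length(t)))
}
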