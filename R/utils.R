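# Internal helpers shared across modules.

# Boltzmann constant times Avogadro, kJ mol^-1 K^-1 (CODATA).
.KB_KJ <- 0.00831446261815324

#' @noRd
kT <- function(temperature) .KB_KJ * temperature

# Evaluate a block with a local RNG stream, restoring the caller's stream.
# All generator entry points route their randomness through this so that a
# fixed seed gives bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Wrap coordinates into [0, box) per dimension (positions: n x 3 matrix).
wrap_positions <- function(pos, box) {
  stopifnot(ncol(pos) == 3L, length(box) == 3L, all(box > 0))
  for (d in 1:3) pos[, d] <- pos[, d] - floor(pos[, d] / box[d]) * box[d]
  pos
}

# Lateral cell index (1-based) for one dimension, with PBC wrap; `n` cells
# spanning [0, L). Used by every gridded statistic so binning is uniform.
cell_index <- function(x, L, n) {
  i <- floor((x %% L) / L * n) + 1L
  i[i > n] <- n  # guard x == L after floating-point wrap
  as.integer(i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
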