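# Shared fixtures, built in code.

# Balanced four-tail composition (equal-abundance tails, 30 mol% sterol):
# isolates co-localization signal from abundance differences.
balanced_comp <- function() {
  read_composition(system.file("extdata", "balanced_tails_composition.csv",
                               package = "memshadow"))
}

# Bundled asymmetric plasma-membrane-like composition, optionally scaled.
pm_comp <- function(scale = 1) {
  comp <- read_composition(system.file(
    "extdata", "plasma_membrane_composition.csv", package = "memshadow"))
  if (scale != 1) {
    e <- comp$entries
    e$count <- as.integer(round(e$count * scale))
    comp <- composition(e)
  }
  comp
}

balanced_tail_targets <- function(comp = balanced_comp(),
                                  tails = c("DA", "DU", "PU", "PI"),
                                  sterol = TRUE) {
  t <- lapply(tails, function(tc) tail_selector(comp, tc))
  names(t) <- tails
  if (sterol) t$CHOL <- sterol_selector(comp)
  t
}

# Hand-rolled frame for geometric unit tests.
toy_frame <- function(pos, box = c(1, 1, 1), resname = NULL) {
  pos <- matrix(pos, ncol = 3, byrow = TRUE)
  n <- nrow(pos)
  if (is.null(resname)) resname <- rep("C60", n)
  frame(pos, resname, rep("F1", n), seq_len(n), box)
}

# Independent clustering oracle: minimum-image distances by explicit
# enumeration of all 27 periodic images (not the package's per-dimension
# folding), components via igraph rather than union-find.
oracle_components <- function(pos, box, cutoff) {
  n <- nrow(pos)
  best <- matrix(Inf, n, n)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    sh <- sweep(pos, 2, c(i, j, k) * box, `+`)
    d2 <- matrix(0, n, n)
    for (d in 1:3) d2 <- d2 + outer(pos[, d], sh[, d], `-`)^2
    best <- pmin(best, d2)
  }
  adj <- best <= cutoff^2
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Compare two cluster labelings as partitions (label-invariant).
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
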