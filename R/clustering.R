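#' Detect particle clusters under periodic boundaries
#'
#' Single-linkage clustering: two particles are connected when their
#' minimum-image distance is at most \code{cutoff}; clusters are the
#' connected components, labeled deterministically in order of each
#' cluster's lowest member index. Distances use the nearest periodic image
#' in all three dimensions, so the cutoff must be below half the smallest
#' box length.
#'
#' Particles are molecules (residues) of the selected species: the position
#' of a multi-bead molecule is its bead centroid.
#'
#' @param frame a [frame].
#' @param selector a [species_selector].
#' @param cutoff contact distance (nm); default 1.0, roughly bead-center
#'   contact for a coarse-grained fullerene.
#' @return a \code{cluster_result}: list with \code{cluster_id} (per
#'   particle, 1-based, contiguous), \code{resid} (particle residue ids),
#'   \code{sizes} (descending), \code{largest_fraction}, \code{n_clusters},
#'   \code{cutoff}.
#' @export
find_clusters <- function(frame, selector, cutoff = 1.0) {
  stopifnot(inherits(frame, "frame"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (cutoff >= min(frame$box) / 2)
    stop("cutoff ", cutoff, " >= half the smallest box length (",
         sprintf("%.3f", min(frame$box) / 2),
         "): minimum-image distances are ambiguous")
  hit <- match_beads_strict(frame, selector)
  pos <- frame$positions[hit, , drop = FALSE]
  rid <- frame$resid[hit]
  # particle = residue centroid
  uq <- unique(rid)
  cen <- t(vapply(uq, function(r)
    colMeans(pos[rid == r, , drop = FALSE]), numeric(3)))
  n <- nrow(cen)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    d2 <- matrix(0, n, n)
    for (d in 1:3) {
      dd <- abs(outer(cen[, d], cen[, d], `-`))
      dd <- pmin(dd, frame$box[d] - dd)
      d2 <- d2 + dd^2
    }
    adj <- which(d2 <= cutoff^2 & upper.tri(d2), arr.ind = TRUE)
    for (k in seq_len(nrow(adj))) {
      a <- find(adj[k, 1]); b <- find(adj[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # deterministic ids: order of lowest member index
  first <- tapply(seq_len(n), root, min)
  relabel <- integer(max(root))
  relabel[as.integer(names(first))] <- rank(first, ties.method = "first")
  cid <- relabel[root]
  sizes <- sort(tabulate(cid), decreasing = TRUE)
  structure(list(cluster_id = cid, resid = uq, sizes = sizes,
                 largest_fraction = sizes[1] / n,
                 n_clusters = length(sizes), cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$cluster_id), "particles,",
      x$n_clusters, "cluster(s); largest",
      sprintf("%.0f%%", 100 * x$largest_fraction),
      "at cutoff", x$cutoff, "nm\n")
  invisible(x)
}

#' Aggregation state over time
#'
#' Runs [find_clusters] per frame and summarizes cluster count, largest
#' cluster size and fraction. The final frame's state is the end-of-run
#' aggregation summary; \code{aggregated} means the largest cluster has at
#' least 2 members.
#'
#' @param traj a [trajectory].
#' @param selector a [species_selector].
#' @param cutoff nm.
#' @return data.frame with columns \code{frame}, \code{n_clusters},
#'   \code{largest_size}, \code{largest_fraction}, \code{aggregated};
#'   attribute \code{final} holds the last row.
#' @export
aggregation_timeseries <- function(traj, selector, cutoff = 1.0) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- lapply(seq_along(traj$frames), function(i) {
    cl <- find_clusters(traj$frames[[i]], selector, cutoff)
    data.frame(frame = i, n_clusters = cl$n_clusters,
               largest_size = cl$sizes[1],
               largest_fraction = cl$largest_fraction,
               aggregated = cl$sizes[1] >= 2L)
  })
  out <- do.call(rbind, rows)
  attr(out, "final") <- out[nrow(out), ]
  attr(out, "cutoff") <- cutoff
  out
}
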