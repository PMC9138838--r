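#' Lateral grid specification
#'
#' A fixed 2D grid over the lateral (x, y) plane. Cell counts are
#' \code{ceiling(box / spacing)}, so when the box is not an exact multiple of
#' the spacing the last row/column of cells is slightly narrower; per-frame
#' boxes are always binned onto the same nx x ny cell topology so matrices
#' stay comparable across frames under a fluctuating box.
#'
#' @param box_x,box_y lateral box lengths (nm).
#' @param spacing target cell edge (nm); default 0.5.
#' @return an object of class \code{grid_spec2d} with fields \code{nx},
#'   \code{ny}, \code{spacing}, \code{box_x}, \code{box_y}.
#' @export
grid_spec2d <- function(box_x, box_y, spacing = 0.5) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (box_x <= 0 || box_y <= 0) stop("box lengths must be > 0")
  structure(list(spacing = spacing,
                 nx = as.integer(ceiling(box_x / spacing)),
                 ny = as.integer(ceiling(box_y / spacing)),
                 box_x = box_x, box_y = box_y),
            class = "grid_spec2d")
}

#' @export
print.grid_spec2d <- function(x, ...) {
  cat("<grid_spec2d>", x$nx, "x", x$ny, "cells, spacing", x$spacing, "nm\n")
  invisible(x)
}

same_grid <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(c(a$box_x, a$box_y), c(b$box_x, b$box_y)))
}

#' Binary shadow matrix of one species
#'
#' Maps the selected beads of one frame onto a lateral grid and records, per
#' cell, whether at least one bead falls in it (1) or none does (0). This is
#' the binary occupancy map underlying the MSE co-localization statistic;
#' occupancy is idempotent — multiple beads in a cell still give 1.
#'
#' @param frame a [frame] (coordinates are wrapped on construction).
#' @param selector a [species_selector]; an error names the selector if it
#'   matches no beads.
#' @param grid a [grid_spec2d]; default: 0.5 nm grid over the frame's box.
#' @param leaflet_scope \code{"both"} (default, pooling both leaflets),
#'   \code{"inner"} or \code{"outer"}; restricting to one leaflet requires
#'   \code{leaflet_bead}.
#' @param leaflet_bead per-bead leaflet labels (from [assign_leaflets] or
#'   generator ground truth), needed when \code{leaflet_scope != "both"}.
#' @return an object of class \code{shadow_matrix}: a binary \code{nx x ny}
#'   integer matrix with attributes \code{grid} and \code{species}.
#' @export
shadow_matrix <- function(frame, selector, grid = NULL,
                          leaflet_scope = c("both", "inner", "outer"),
                          leaflet_bead = NULL) {
  leaflet_scope <- match.arg(leaflet_scope)
  stopifnot(inherits(frame, "frame"))
  if (is.null(grid)) grid <- grid_spec2d(frame$box[1], frame$box[2])
  hit <- match_beads_strict(frame, selector)
  if (leaflet_scope != "both") {
    if (is.null(leaflet_bead))
      stop("leaflet_scope='", leaflet_scope,
           "' requires per-bead leaflet labels (leaflet_bead=)")
    hit <- hit & (leaflet_bead == leaflet_scope)
    if (!any(hit))
      stop("selector '", selector$label, "' matches no beads in leaflet ",
           leaflet_scope)
  }
  pos <- frame$positions[hit, , drop = FALSE]
  ix <- cell_index(pos[, 1], frame$box[1], grid$nx)
  iy <- cell_index(pos[, 2], frame$box[2], grid$ny)
  m <- matrix(0L, grid$nx, grid$ny)
  m[cbind(ix, iy)] <- 1L
  structure(m, grid = grid, species = selector$label,
            class = c("shadow_matrix", "matrix"))
}

#' @export
print.shadow_matrix <- function(x, ...) {
  g <- attr(x, "grid")
  cat("<shadow_matrix>", attr(x, "species"), "-", g$nx, "x", g$ny,
      "cells,", sum(x), "occupied",
      sprintf("(%.1f%%)\n", 100 * mean(x)))
  invisible(x)
}

#' Mean square error between two shadow matrices
#'
#' \code{mean((a - b)^2)} over cells. For binary occupancy matrices this is
#' the fraction of mismatched cells: 0 means the two species occupy exactly
#' the same cells, 1 means complementary occupancy. Symmetric and bounded in
#' \code{[0, 1]} for binary input.
#'
#' @param a,b \code{shadow_matrix} objects on the same grid (plain numeric
#'   matrices of equal dimension are also accepted).
#' @return a single number.
#' @export
mse <- function(a, b) {
  ga <- attr(a, "grid"); gb <- attr(b, "grid")
  if (!is.null(ga) && !is.null(gb) && !same_grid(ga, gb))
    stop("shadow matrices are on different grids")
  if (!identical(dim(a), dim(b)))
    stop("shadow matrices have different dimensions")
  mean((unclass(a) - unclass(b))^2)
}

#' Ranked co-localization table
#'
#' For each frame in range, builds the reference species' shadow matrix and
#' one per target on a shared grid, computes the pairwise MSE, and reports
#' per-target mean and standard error over frames, ranked ascending (smallest
#' MSE = strongest co-localization first). This reproduces the ranking logic
#' of shadow-matrix co-localization tables: the tail type whose lateral
#' domains best match the nanoparticle positions ranks first.
#'
#' @param traj a [trajectory].
#' @param reference [species_selector] for the reference species
#'   (nanoparticle).
#' @param targets named list of [species_selector]s (e.g. one per tail code
#'   plus sterol); names default to selector labels.
#' @param grid_spacing nm, default 0.5.
#' @param frame_range integer vector of frame indices; default all frames.
#' @param mode \code{"per_frame"} (default): MSE per frame then averaged,
#'   which also yields the standard error; \code{"time_average"}: one MSE
#'   between time-averaged occupancy matrices (binarized by any-occupancy).
#' @return a \code{colocal_table}: data.frame with columns \code{species},
#'   \code{mean_mse}, \code{se}, \code{rank}, \code{tied}, sorted ascending
#'   by \code{mean_mse} (ties broken by species label, flagged).
#' @export
colocalization_table <- function(traj, reference, targets,
                                 grid_spacing = 0.5, frame_range = NULL,
                                 mode = c("per_frame", "time_average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frame_range)) frame_range <- seq_along(traj$frames)
  if (!length(frame_range)) stop("empty frame range")
  if (any(frame_range < 1L | frame_range > length(traj$frames)))
    stop("frame_range out of bounds")
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, `[[`, character(1), "label")
  fr1 <- traj$frames[[frame_range[1]]]
  grid <- grid_spec2d(fr1$box[1], fr1$box[2], grid_spacing)
  nt <- length(targets)
  mses <- matrix(NA_real_, length(frame_range), nt,
                 dimnames = list(NULL, names(targets)))
  if (mode == "time_average") {
    acc_ref <- matrix(0L, grid$nx, grid$ny)
    acc_tgt <- lapply(seq_len(nt), function(i) matrix(0L, grid$nx, grid$ny))
  }
  for (k in seq_along(frame_range)) {
    fr <- traj$frames[[frame_range[k]]]
    ref <- shadow_matrix(fr, reference, grid)
    for (i in seq_len(nt)) {
      tgt <- shadow_matrix(fr, targets[[i]], grid)
      if (mode == "per_frame") mses[k, i] <- mse(ref, tgt)
      else acc_tgt[[i]] <- acc_tgt[[i]] | tgt
    }
    if (mode == "time_average") acc_ref <- acc_ref | ref
  }
  if (mode == "per_frame") {
    mean_mse <- colMeans(mses)
    se <- apply(mses, 2, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  } else {
    mean_mse <- vapply(acc_tgt, function(m)
      mean((m * 1L - acc_ref * 1L)^2), numeric(1))
    names(mean_mse) <- names(targets)
    se <- rep(NA_real_, nt)
  }
  ord <- order(mean_mse, names(targets))  # ties broken lexicographically
  tab <- data.frame(species = names(targets)[ord],
                    mean_mse = unname(mean_mse[ord]),
                    se = unname(se[ord]),
                    rank = seq_len(nt),
                    stringsAsFactors = FALSE)
  tab$tied <- duplicated(tab$mean_mse) | duplicated(tab$mean_mse,
                                                    fromLast = TRUE)
  attr(tab, "n_frames") <- length(frame_range)
  attr(tab, "grid_spacing") <- grid_spacing
  attr(tab, "mode") <- mode
  class(tab) <- c("colocal_table", "data.frame")
  tab
}

#' Top-k extremes of a co-localization table
#'
#' @param table a \code{colocal_table}.
#' @param k how many entries per end (default 5).
#' @return list with \code{smallest} (strongest co-localization) and
#'   \code{largest} (strongest avoidance) sub-tables.
#' @export
colocal_extremes <- function(table, k = 5L) {
  stopifnot(inherits(table, "colocal_table"))
  n <- nrow(table)
  list(smallest = utils::head(table, min(k, n)),
       largest = utils::tail(table, min(k, n))[order(
         utils::tail(table$mean_mse, min(k, n)), decreasing = TRUE), ])
}

#' @export
print.colocal_table <- function(x, ...) {
  cat("<colocal_table>", nrow(x), "targets over", attr(x, "n_frames"),
      "frame(s), grid", attr(x, "grid_spacing"), "nm, mode",
      attr(x, "mode"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
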