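#' Assign lipids to leaflets by local midplane
#'
#' Estimates a local bilayer midplane on a coarse lateral grid as the
#' count-weighted mean phosphate z per cell, smoothed over the 3 x 3 cell
#' neighbourhood (periodic), then labels each lipid \code{"inner"} (below the
#' local midplane) or \code{"outer"} (above). Lipids carrying a phosphate
#' bead are placed by that bead's z; sterols and other phosphate-free
#' residues by their mean bead z, which assigns them to the nearest
#' phosphate layer. A local-midplane (rather than global-plane) rule is used
#' because undulating membranes can locally displace both leaflets past the
#' global mean.
#'
#' @param frame a [frame].
#' @param phosphate_selector [species_selector] for phosphate beads; default
#'   matches bead name \code{PO4}.
#' @param cell lateral cell edge for the midplane estimate (nm, default 2).
#' @param exclude residue names to leave unlabeled (water/ions); nanoparticle
#'   residues get label \code{"np"}.
#' @param np_resnames residue names treated as nanoparticle.
#' @return list with \code{lipid} (data.frame: resid, resname, leaflet),
#'   \code{bead} (per-bead label vector), and \code{midplane} (the cell-grid
#'   height field, an nx x ny matrix).
#' @export
assign_leaflets <- function(frame,
                            phosphate_selector = species_selector(
                              beads = "^PO4$", label = "PO4"),
                            cell = 2, exclude = c("W", "WN", "ION", "NA+",
                                                  "CL-", "NA", "CL"),
                            np_resnames = "C60") {
  stopifnot(inherits(frame, "frame"))
  ph <- match_beads(frame, phosphate_selector)
  if (sum(ph) < 2L) stop("need at least 2 phosphate beads to assign leaflets")
  Lx <- frame$box[1]; Ly <- frame$box[2]
  nx <- max(1L, as.integer(round(Lx / cell)))
  ny <- max(1L, as.integer(round(Ly / cell)))
  px <- frame$positions[ph, 1]; py <- frame$positions[ph, 2]
  pz <- frame$positions[ph, 3]
  ix <- cell_index(px, Lx, nx); iy <- cell_index(py, Ly, ny)
  sumz <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  for (k in seq_along(pz)) {
    sumz[ix[k], iy[k]] <- sumz[ix[k], iy[k]] + pz[k]
    cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  }
  # periodic 3x3 neighbourhood smoothing of the count-weighted field
  shift <- function(m, dx, dy) {
    m[((seq_len(nx) - 1L - dx) %% nx) + 1L,
      ((seq_len(ny) - 1L - dy) %% ny) + 1L, drop = FALSE]
  }
  sz <- matrix(0, nx, ny); ct <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    sz <- sz + shift(sumz, dx, dy)
    ct <- ct + shift(cnt, dx, dy)
  }
  hfield <- sz / ct
  empty <- ct == 0
  if (any(empty)) {
    warning(sum(empty), " lateral cell(s) have no phosphates within the ",
            "smoothing radius; lipids there labeled by the global midplane")
    hfield[empty] <- mean(pz)
  }

  # reference z per residue: phosphate bead if present, else mean bead z
  resid <- frame$resid
  zb <- frame$positions[, 3]
  ref_z <- tapply(zb, resid, mean)
  ph_z <- tapply(ifelse(ph, zb, NA_real_), resid, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  use <- !is.na(ph_z)
  ref_z[use] <- ph_z[use]
  ref_x <- tapply(frame$positions[, 1], resid, mean)
  ref_y <- tapply(frame$positions[, 2], resid, mean)
  res_ids <- as.integer(names(ref_z))
  res_name <- frame$resname[match(res_ids, resid)]

  hx <- cell_index(ref_x, Lx, nx); hy <- cell_index(ref_y, Ly, ny)
  local_h <- hfield[cbind(hx, hy)]
  leaflet <- ifelse(ref_z >= local_h, "outer", "inner")
  leaflet[res_name %in% exclude] <- NA_character_
  leaflet[res_name %in% np_resnames] <- "np"

  lipid <- data.frame(resid = res_ids, resname = res_name,
                      leaflet = unname(leaflet), stringsAsFactors = FALSE)
  bead <- lipid$leaflet[match(resid, lipid$resid)]
  list(lipid = lipid, bead = bead, midplane = hfield)
}

#' z-density profile in the bilayer-center frame
#'
#' Per frame, re-centers z to the instantaneous bilayer center — the
#' midpoint between the mean inner- and mean outer-leaflet phosphate z
#' (robust to leaflets with unequal phosphate counts) — and accumulates
#' per-species histograms, averaged over frames.
#' The count integral is conserved: summed counts equal the mean number of
#' selected beads per frame.
#'
#' @param traj a [trajectory].
#' @param selectors named list of [species_selector]s.
#' @param bin_width nm, default 0.1.
#' @param phosphate_selector selector defining the bilayer center.
#' @param center re-center to the bilayer midplane (default TRUE).
#' @return a \code{density_profile}: data.frame with \code{z} (bin centers,
#'   nm from bilayer center), one mean-count column and one number-density
#'   column (nm^-3) per species; attributes \code{bin_width},
#'   \code{n_frames}.
#' @export
density_profile <- function(traj, selectors, bin_width = 0.1,
                            phosphate_selector = species_selector(
                              beads = "^PO4$", label = "PO4"),
                            center = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(names(selectors)))
    names(selectors) <- vapply(selectors, `[[`, character(1), "label")
  nf <- length(traj$frames)
  frame_center <- function(fr) {
    if (!center) return(0)
    ph <- match_beads_strict(fr, phosphate_selector)
    lab <- assign_leaflets(fr, phosphate_selector)$bead
    zo <- fr$positions[ph & !is.na(lab) & lab == "outer", 3]
    zi <- fr$positions[ph & !is.na(lab) & lab == "inner", 3]
    if (!length(zo) || !length(zi)) mean(fr$positions[ph, 3])
    else (mean(zo) + mean(zi)) / 2
  }
  # common edges: widest recentered z range across frames, 0 on an edge
  zr <- range(vapply(traj$frames, function(fr)
    range(fr$positions[, 3] - frame_center(fr)), numeric(2)))
  lo <- floor(zr[1] / bin_width) * bin_width
  hi <- ceiling(zr[2] / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  mids <- edges[-length(edges)] + bin_width / 2
  counts <- matrix(0, length(mids), length(selectors),
                   dimnames = list(NULL, names(selectors)))
  for (fr in traj$frames) {
    c0 <- frame_center(fr)
    for (i in seq_along(selectors)) {
      z <- fr$positions[match_beads_strict(fr, selectors[[i]]), 3] - c0
      b <- pmin(pmax(floor((z - lo) / bin_width) + 1L, 1L), length(mids))
      counts[, i] <- counts[, i] + tabulate(b, nbins = length(mids))
    }
  }
  counts <- counts / nf
  area <- traj$frames[[1]]$box[1] * traj$frames[[1]]$box[2]
  dens <- counts / (bin_width * area)
  colnames(dens) <- paste0(colnames(counts), "_density")
  out <- data.frame(z = mids, counts, dens, check.names = FALSE)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- nf
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Lateral enrichment/depletion map
#'
#' Time-averaged lateral bead counts per grid cell, divided by the lateral
#' mean count, so 1 is neutral, values above 1 are enrichment and below 1
#' depletion. The map mean is exactly 1 by construction.
#'
#' @param traj a [trajectory].
#' @param selector a [species_selector].
#' @param grid_spacing nm, default 1.
#' @param leaflet_scope \code{"both"}, \code{"inner"} or \code{"outer"};
#'   non-pooled scopes assign leaflets per frame via [assign_leaflets].
#' @return an \code{enrichment_map}: numeric nx x ny matrix (attribute
#'   \code{grid}).
#' @export
enrichment_map <- function(traj, selector, grid_spacing = 1,
                           leaflet_scope = c("both", "inner", "outer")) {
  leaflet_scope <- match.arg(leaflet_scope)
  stopifnot(inherits(traj, "trajectory"))
  fr1 <- traj$frames[[1]]
  grid <- grid_spec2d(fr1$box[1], fr1$box[2], grid_spacing)
  acc <- matrix(0, grid$nx, grid$ny)
  for (fr in traj$frames) {
    hit <- match_beads_strict(fr, selector)
    if (leaflet_scope != "both") {
      lab <- assign_leaflets(fr)$bead
      hit <- hit & !is.na(lab) & lab == leaflet_scope
    }
    pos <- fr$positions[hit, , drop = FALSE]
    ix <- cell_index(pos[, 1], fr$box[1], grid$nx)
    iy <- cell_index(pos[, 2], fr$box[2], grid$ny)
    acc <- acc + matrix(tabulate((iy - 1L) * grid$nx + ix,
                                 nbins = grid$nx * grid$ny),
                        grid$nx, grid$ny)
  }
  if (sum(acc) == 0) stop("zero total density for selector '",
                          selector$label, "'")
  vals <- acc / mean(acc)
  structure(vals, grid = grid, species = selector$label,
            n_frames = length(traj$frames),
            class = c("enrichment_map", "matrix"))
}

#' Local bilayer thickness map
#'
#' Per lateral cell, thickness is the mean outer-leaflet phosphate z minus
#' the mean inner-leaflet phosphate z, averaged over frames. Leaflets are
#' taken from [assign_leaflets] per frame. Cells never covered by both
#' leaflets are masked (\code{NA}). Residues without phosphate beads
#' (glycolipids, ceramides, sterols) do not contribute.
#'
#' @param traj a [trajectory].
#' @param phosphate_selector phosphate-bead selector.
#' @param grid_spacing nm, default 1.
#' @return a \code{thickness_map}: numeric nx x ny matrix in nm with
#'   \code{NA} where uncovered; attributes \code{grid}, \code{coverage}
#'   (frames contributing per cell).
#' @export
thickness_map <- function(traj, phosphate_selector = species_selector(
                            beads = "^PO4$", label = "PO4"),
                          grid_spacing = 1) {
  stopifnot(inherits(traj, "trajectory"))
  fr1 <- traj$frames[[1]]
  grid <- grid_spec2d(fr1$box[1], fr1$box[2], grid_spacing)
  sumt <- matrix(0, grid$nx, grid$ny)
  cov <- matrix(0L, grid$nx, grid$ny)
  for (fr in traj$frames) {
    ph <- match_beads_strict(fr, phosphate_selector)
    lab <- assign_leaflets(fr, phosphate_selector)$bead
    if (!any(lab[ph] == "inner", na.rm = TRUE) ||
        !any(lab[ph] == "outer", na.rm = TRUE))
      stop("both leaflets must contain phosphates")
    pos <- fr$positions[ph, , drop = FALSE]
    lf <- lab[ph]
    ix <- cell_index(pos[, 1], fr$box[1], grid$nx)
    iy <- cell_index(pos[, 2], fr$box[2], grid$ny)
    cid <- (iy - 1L) * grid$nx + ix
    ncell <- grid$nx * grid$ny
    accum <- function(sel) {
      s <- numeric(ncell); n <- integer(ncell)
      if (any(sel)) {
        t1 <- rowsum(pos[sel, 3], cid[sel])
        t2 <- rowsum(rep(1L, sum(sel)), cid[sel])
        at <- as.integer(rownames(t1))
        s[at] <- t1[, 1]; n[at] <- t2[, 1]
      }
      list(s = matrix(s, grid$nx, grid$ny), n = matrix(n, grid$nx, grid$ny))
    }
    o <- accum(!is.na(lf) & lf == "outer")
    i_ <- accum(!is.na(lf) & lf == "inner")
    so <- o$s; no <- o$n; si <- i_$s; ni <- i_$n
    ok <- no > 0L & ni > 0L
    sumt[ok] <- sumt[ok] + (so[ok] / no[ok] - si[ok] / ni[ok])
    cov[ok] <- cov[ok] + 1L
  }
  if (all(cov == 0L)) stop("no lateral cell is covered by both leaflets")
  vals <- ifelse(cov > 0L, sumt / pmax(cov, 1L), NA_real_)
  structure(vals, grid = grid, coverage = cov,
            n_frames = length(traj$frames),
            class = c("thickness_map", "matrix"))
}

#' Midplane undulation metrics
#'
#' Builds the midplane height field h(x, y) per frame on a coarse lateral
#' grid: phosphates are assigned to leaflets by [assign_leaflets], and per
#' cell h is the average of the outer- and inner-leaflet mean z. Cells
#' covered by only one leaflet are filled by iterative periodic
#' nearest-neighbour averaging, which preserves long-wavelength modes.
#' Reports the RMS height fluctuation and the
#' discrete Fourier amplitude spectrum of the lowest lateral modes,
#' averaged over frames.
#'
#' @param traj a [trajectory].
#' @param phosphate_selector phosphate-bead selector.
#' @param cell lateral cell edge (nm, default 2).
#' @param n_modes report modes with wave indices up to this value (default 3).
#' @return list with \code{rms} (nm), \code{spectrum} (data.frame: p, q,
#'   amplitude in nm) and \code{hfield} (last frame's height field).
#' @export
undulation_metric <- function(traj, phosphate_selector = species_selector(
                                beads = "^PO4$", label = "PO4"),
                              cell = 2, n_modes = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  fr1 <- traj$frames[[1]]
  Lx <- fr1$box[1]; Ly <- fr1$box[2]
  nx <- max(2L, as.integer(round(Lx / cell)))
  ny <- max(2L, as.integer(round(Ly / cell)))
  rms_acc <- 0
  amp_acc <- matrix(0, nx, ny)
  hfield <- NULL
  for (fr in traj$frames) {
    ph <- match_beads_strict(fr, phosphate_selector)
    lab <- assign_leaflets(fr, phosphate_selector)$bead
    pos <- fr$positions[ph, , drop = FALSE]
    lf <- lab[ph]
    ix <- cell_index(pos[, 1], Lx, nx)
    iy <- cell_index(pos[, 2], Ly, ny)
    cid <- (iy - 1L) * nx + ix
    h <- rep(NA_real_, nx * ny)
    for (cc in unique(cid)) {
      z <- pos[cid == cc, 3]
      l <- lf[cid == cc]
      zo <- z[!is.na(l) & l == "outer"]; zi <- z[!is.na(l) & l == "inner"]
      if (length(zo) && length(zi)) h[cc] <- (mean(zo) + mean(zi)) / 2
    }
    hfield <- fill_periodic(matrix(h, nx, ny))
    dh <- hfield - mean(hfield)
    rms_acc <- rms_acc + sqrt(mean(dh^2))
    amp_acc <- amp_acc + Mod(stats::fft(dh)) * 2 / (nx * ny)
  }
  nf <- length(traj$frames)
  amp <- amp_acc / nf
  sp <- expand.grid(p = 0:min(n_modes, nx - 1L), q = 0:min(n_modes, ny - 1L))
  sp <- sp[!(sp$p == 0 & sp$q == 0), ]
  sp$amplitude <- amp[cbind(sp$p + 1L, sp$q + 1L)]
  sp <- sp[order(-sp$amplitude), ]
  rownames(sp) <- NULL
  list(rms = rms_acc / nf, spectrum = sp, hfield = hfield)
}

# Fill NA cells of a periodic matrix by repeated 4-neighbour averaging of
# the already-known cells, propagating inward until all cells are defined.
fill_periodic <- function(m) {
  if (!anyNA(m)) return(m)
  nx <- nrow(m); ny <- ncol(m)
  up <- function(i, n) ifelse(i == n, 1L, i + 1L)
  dn <- function(i, n) ifelse(i == 1L, n, i - 1L)
  guard <- 0L
  while (anyNA(m) && guard < nx * ny) {
    guard <- guard + 1L
    na_idx <- which(is.na(m), arr.ind = TRUE)
    vals <- numeric(nrow(na_idx)); got <- logical(nrow(na_idx))
    for (k in seq_len(nrow(na_idx))) {
      i <- na_idx[k, 1]; j <- na_idx[k, 2]
      nb <- c(m[up(i, nx), j], m[dn(i, nx), j],
              m[i, up(j, ny)], m[i, dn(j, ny)])
      if (any(!is.na(nb))) { vals[k] <- mean(nb, na.rm = TRUE); got[k] <- TRUE }
    }
    if (!any(got)) break
    m[na_idx[got, , drop = FALSE]] <- vals[got]
  }
  if (anyNA(m)) m[is.na(m)] <- mean(m, na.rm = TRUE)
  m
}

#' Tail-unsaturation distribution per leaflet
#'
#' Tallies lipid tails into double-bond classes 0-6, weighted by lipid
#' counts, separately for the inner and outer leaflet, and normalizes to
#' mole fractions of tails. Residues with leaflet \code{"both"} contribute
#' half their count to each leaflet; tail-less residues (sterols,
#' nanoparticles) are excluded.
#'
#' @param composition a [composition].
#' @return an \code{unsaturation_histogram}: data.frame with columns
#'   \code{db} (0-6), \code{inner}, \code{outer} (mole fractions, each
#'   summing to 1).
#' @export
unsaturation_histogram <- function(composition) {
  stopifnot(inherits(composition, "composition"))
  e <- composition$entries
  tally <- function(which_leaflet) {
    h <- numeric(7)
    for (i in seq_len(nrow(e))) {
      w <- switch(e$leaflet[i],
                  inner = if (which_leaflet == "inner") e$count[i] else 0,
                  outer = if (which_leaflet == "outer") e$count[i] else 0,
                  both = e$count[i] / 2,
                  0)
      if (w == 0) next
      if (!is.na(e$tail1[i])) h[e$db1[i] + 1L] <- h[e$db1[i] + 1L] + w
      if (!is.na(e$tail2[i])) h[e$db2[i] + 1L] <- h[e$db2[i] + 1L] + w
    }
    h
  }
  hi <- tally("inner"); ho <- tally("outer")
  if (sum(hi) == 0) stop("inner leaflet has no lipid tails")
  if (sum(ho) == 0) stop("outer leaflet has no lipid tails")
  out <- data.frame(db = 0:6, inner = hi / sum(hi), outer = ho / sum(ho))
  class(out) <- c("unsaturation_histogram", "data.frame")
  out
}
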