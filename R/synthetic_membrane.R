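#' Synthetic membrane specification
#'
#' Parameters for the ground-truth membrane generator. The generator emulates
#' the lateral organisation of an asymmetric multicomponent bilayer — two
#' leaflets of labeled lipids on jittered lattices, tail-type domains from a
#' thresholded Gaussian random field, cosine-mode undulations of the midplane,
#' and nanoparticle beads near the midplane with tunable co-localization to
#' one tail type — without any force field or dynamics. Every planted feature
#' is returned as ground truth so analyses can be validated by parameter
#' recovery.
#'
#' @param composition a [composition] giving per-residue counts and leaflets.
#' @param box box lengths (nm); default \code{c(40, 40, 13)}.
#' @param leaflet_z_offset distance from midplane to each phosphate plane
#'   (nm); default 2.
#' @param np_count number of nanoparticle molecules.
#' @param np_colocal_target tail code the nanoparticles co-localize with, or
#'   \code{"none"}.
#' @param np_colocal_strength mixing weight in \code{[0, 1]}: 0 = uniform
#'   lateral placement, 1 = fully confined to the target tail's domains.
#' @param undulation_amplitude per-mode amplitude of midplane undulations (nm).
#' @param undulation_modes number of planted cosine modes (lowest wavevectors).
#' @param cluster_fraction fraction of nanoparticles placed in one planted
#'   contact-distance cluster.
#' @param patch_correlation_length correlation length of the tail-domain
#'   field (nm); default 5.
#' @param thickness_bump_amplitude local thickness increase planted under the
#'   nanoparticle cluster (nm); 0 disables.
#' @param thickness_bump_sigma Gaussian radius of the thickness bump (nm).
#' @param np_bead_expansion if \code{TRUE}, each nanoparticle is written as a
#'   16-bead shell (I/O realism); default single bead.
#' @param seed integer RNG seed; the generator is bit-deterministic under it.
#' @return an object of class \code{membrane_spec}.
#' @export
membrane_spec <- function(composition,
                          box = c(40, 40, 13),
                          leaflet_z_offset = 2.0,
                          np_count = 0L,
                          np_colocal_target = "none",
                          np_colocal_strength = 0,
                          undulation_amplitude = 0,
                          undulation_modes = 1L,
                          cluster_fraction = 0,
                          patch_correlation_length = 5,
                          thickness_bump_amplitude = 0,
                          thickness_bump_sigma = 3,
                          np_bead_expansion = FALSE,
                          seed = 1L) {
  stopifnot(inherits(composition, "composition"))
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  if (leaflet_z_offset <= 0 || leaflet_z_offset >= box[3] / 2)
    stop("leaflet_z_offset must lie in (0, box_z/2)")
  if (np_count < 0) stop("np_count must be >= 0")
  for (v in c(np_colocal_strength, cluster_fraction))
    if (v < 0 || v > 1) stop("strengths/fractions must lie in [0, 1]")
  if (undulation_amplitude < 0) stop("undulation_amplitude must be >= 0")
  if (np_colocal_target != "none") {
    e <- composition$entries
    tails <- unique(stats::na.omit(c(e$tail1, e$tail2)))
    if (!np_colocal_target %in% tails)
      stop("unknown tail code '", np_colocal_target, "' in composition")
  }
  lc <- leaflet_counts(composition)
  area <- box[1] * box[2]
  # sterols intercalate between chains and contribute almost no lateral
  # area in condensed membranes, so the ~0.6 nm^2/lipid crowding check
  # counts phospholipids only
  e0 <- composition$entries
  sterols <- e0$residue[e0$headgroup == "CHOL"]
  nmax <- max(sum(lc$inner[!names(lc$inner) %in% sterols]),
              sum(lc$outer[!names(lc$outer) %in% sterols]))
  if (nmax * 0.6 > area)
    stop("overcrowded leaflet: ", nmax, " phospholipids need ",
         sprintf("%.0f", nmax * 0.6), " nm^2 > lateral area ",
         sprintf("%.0f", area), " nm^2")
  structure(list(composition = composition, box = box,
                 leaflet_z_offset = leaflet_z_offset,
                 np_count = as.integer(np_count),
                 np_colocal_target = np_colocal_target,
                 np_colocal_strength = np_colocal_strength,
                 undulation_amplitude = undulation_amplitude,
                 undulation_modes = as.integer(undulation_modes),
                 cluster_fraction = cluster_fraction,
                 patch_correlation_length = patch_correlation_length,
                 thickness_bump_amplitude = thickness_bump_amplitude,
                 thickness_bump_sigma = thickness_bump_sigma,
                 np_bead_expansion = isTRUE(np_bead_expansion),
                 seed = as.integer(seed)),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("<membrane_spec> box", paste(sprintf("%.1f", x$box), collapse = " x "),
      "nm;", sum(x$composition$entries$count), "lipids;",
      x$np_count, "NPs (target", x$np_colocal_target,
      "strength", x$np_colocal_strength, ")\n")
  invisible(x)
}

# Lowest distinct lateral wavevectors, used in planted order.
.WAVEVECTORS <- rbind(c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2),
                      c(2, 1), c(1, 2), c(2, 2), c(3, 0), c(0, 3))

# Gaussian-random-field evaluator: sum of K cosine modes with wavelength near
# `corr` (periodic in the box). Returns function(x, y).
make_patch_field <- function(Lx, Ly, corr, K = 8L) {
  th <- stats::runif(K, 0, 2 * pi)
  p <- round(Lx / corr * cos(th))
  q <- round(Ly / corr * sin(th))
  zero <- p == 0 & q == 0
  p[zero] <- 1
  a <- stats::rnorm(K)
  ph <- stats::runif(K, 0, 2 * pi)
  function(x, y) {
    s <- 0
    for (j in seq_len(K))
      s <- s + a[j] * cos(2 * pi * (p[j] * x / Lx + q[j] * y / Ly) + ph[j])
    s
  }
}

#' Build a synthetic membrane with planted ground truth
#'
#' Generates \code{n_frames} snapshots from a [membrane_spec]. Lipids sit on
#' per-leaflet jittered lattices; lipids carrying the co-localization target
#' tail occupy the high-field sites of a thresholded Gaussian random field
#' (domains), sterols the low-field sites (planted anti-correlation), other
#' species random sites. Head beads sit exactly on the local leaflet surface
#' (midplane plus/minus offset, following planted undulations and thickness
#' bump); tail beads hang toward the midplane with small lateral jitter.
#' Nanoparticles sit near the midplane; a \code{cluster_fraction} of them
#' forms one contact-distance cluster. Across frames the lipid sites are
#' fixed while tail jitter and nanoparticle positions are redrawn, emulating
#' fast nanoparticle diffusion over a static domain pattern.
#'
#' @param spec a [membrane_spec].
#' @param n_frames number of snapshots.
#' @return a list with elements \code{trajectory} (a [trajectory]) and
#'   \code{truth} (planted leaflet labels, cluster membership, domain field,
#'   midplane and thickness functions, undulation mode table).
#' @export
build_membrane <- function(spec, n_frames = 1L) {
  stopifnot(inherits(spec, "membrane_spec"), n_frames >= 1L)
  with_seed(spec$seed, build_membrane_impl(spec, as.integer(n_frames)))
}

build_membrane_impl <- function(spec, n_frames) {
  comp <- spec$composition
  e <- comp$entries
  Lx <- spec$box[1]; Ly <- spec$box[2]; zmid0 <- spec$box[3] / 2
  off <- spec$leaflet_z_offset
  lc <- leaflet_counts(comp)
  target <- spec$np_colocal_target

  # --- planted lateral domain field -----------------------------------------
  field <- NULL; thr <- NA_real_; patch_cells <- NULL; fine <- NULL
  if (target != "none") {
    field <- make_patch_field(Lx, Ly, spec$patch_correlation_length)
    nfx <- max(8L, round(Lx / 0.25)); nfy <- max(8L, round(Ly / 0.25))
    fx <- (seq_len(nfx) - 0.5) / nfx * Lx
    fy <- (seq_len(nfy) - 0.5) / nfy * Ly
    fv <- outer(fx, fy, field)
    # patch area fraction = target share of the leaflet(s) it occupies, so
    # the planted domains have the same lateral extent as the target lipids
    has_t <- vapply(seq_len(nrow(e)), function(i)
      (!is.na(e$tail1[i]) && e$tail1[i] == target) ||
        (!is.na(e$tail2[i]) && e$tail2[i] == target), logical(1))
    cnt_t <- function(lfc) sum(lfc[names(lfc) %in% e$residue[has_t]])
    n_in_t <- cnt_t(lc$inner); n_out_t <- cnt_t(lc$outer)
    denom <- sum(lc$inner) * (n_in_t > 0) + sum(lc$outer) * (n_out_t > 0)
    frac_t <- min(0.9, max(0.02, (n_in_t + n_out_t) / max(1L, denom)))
    thr <- stats::quantile(fv, 1 - frac_t, names = FALSE)
    idx <- which(fv >= thr, arr.ind = TRUE)
    patch_cells <- cbind(fx[idx[, 1]], fy[idx[, 2]])
    fine <- list(dx = Lx / nfx, dy = Ly / nfy)
  }

  # --- planted undulation modes ---------------------------------------------
  nm <- min(spec$undulation_modes, nrow(.WAVEVECTORS))
  und <- data.frame(p = .WAVEVECTORS[seq_len(nm), 1],
                    q = .WAVEVECTORS[seq_len(nm), 2],
                    amplitude = rep(spec$undulation_amplitude, nm),
                    phase = stats::runif(nm, 0, 2 * pi))
  if (spec$undulation_amplitude == 0) und$amplitude <- rep(0, nm)
  midplane <- function(x, y) {
    h <- rep(zmid0, length(x))
    for (j in seq_len(nrow(und)))
      h <- h + und$amplitude[j] *
        cos(2 * pi * (und$p[j] * x / Lx + und$q[j] * y / Ly) + und$phase[j])
    h
  }

  # --- per-leaflet site assignment ------------------------------------------
  assign_leaflet_sites <- function(counts) {
    n <- sum(counts)
    if (n == 0L) return(NULL)
    m <- ceiling(sqrt(n))
    gx <- ((seq_len(m) - 0.5) / m) * Lx
    gy <- ((seq_len(m) - 0.5) / m) * Ly
    sites <- expand.grid(x = gx, y = gy)
    sites$x <- sites$x + stats::runif(m * m, -0.3, 0.3) * (Lx / m)
    sites$y <- sites$y + stats::runif(m * m, -0.3, 0.3) * (Ly / m)
    sites <- sites[sample.int(m * m, n), , drop = FALSE]
    resn <- rep(names(counts), counts)
    if (!is.null(field)) {
      fv <- field(sites$x, sites$y)
      ord <- order(fv, decreasing = TRUE)
      is_t <- vapply(resn, function(r) {
        i <- match(r, e$residue)
        (!is.na(e$tail1[i]) && e$tail1[i] == target) ||
          (!is.na(e$tail2[i]) && e$tail2[i] == target)
      }, logical(1))
      is_s <- e$headgroup[match(resn, e$residue)] == "CHOL"
      resample <- function(x) x[sample.int(length(x))]
      slot <- integer(n)
      nt <- sum(is_t); ns <- sum(is_s & !is_t)
      slot[is_t] <- resample(ord[seq_len(nt)])
      slot[is_s & !is_t] <- resample(if (ns) ord[(n - ns + 1L):n] else integer(0))
      rest <- !(is_t | (is_s & !is_t))
      mid <- setdiff(seq_len(n), c(seq_len(nt), if (ns) (n - ns + 1L):n))
      slot[rest] <- resample(ord[mid])
      sites <- sites[slot, , drop = FALSE]
    } else {
      resn <- resn[sample.int(n)]
    }
    data.frame(x = sites$x, y = sites$y, residue = resn,
               stringsAsFactors = FALSE)
  }
  inner <- assign_leaflet_sites(lc$inner)
  outer_ <- assign_leaflet_sites(lc$outer)

  # --- nanoparticle cluster layout ------------------------------------------
  np <- spec$np_count
  n_clustered <- round(spec$cluster_fraction * np)
  draw_np_xy <- function(k) {
    if (k == 0L) return(matrix(numeric(0), 0, 2))
    use_patch <- if (is.null(patch_cells)) rep(FALSE, k)
                 else stats::runif(k) < spec$np_colocal_strength
    out <- matrix(0, k, 2)
    n_p <- sum(use_patch)
    if (n_p) {
      ci <- sample.int(nrow(patch_cells), n_p, replace = TRUE)
      out[use_patch, 1] <- patch_cells[ci, 1] +
        stats::runif(n_p, -0.5, 0.5) * fine$dx
      out[use_patch, 2] <- patch_cells[ci, 2] +
        stats::runif(n_p, -0.5, 0.5) * fine$dy
    }
    n_u <- k - n_p
    if (n_u) {
      out[!use_patch, 1] <- stats::runif(n_u, 0, Lx)
      out[!use_patch, 2] <- stats::runif(n_u, 0, Ly)
    }
    out
  }
  cluster_center <- NULL
  if (n_clustered > 0L) cluster_center <- draw_np_xy(1L)[1, ]

  # --- thickness bump (under the planted cluster, else box center) ----------
  bump_center <- if (!is.null(cluster_center)) cluster_center
                 else c(Lx / 2, Ly / 2)
  bump <- function(x, y) {
    if (spec$thickness_bump_amplitude == 0) return(rep(0, length(x)))
    dx <- abs(x - bump_center[1]); dx <- pmin(dx, Lx - dx)
    dy <- abs(y - bump_center[2]); dy <- pmin(dy, Ly - dy)
    spec$thickness_bump_amplitude *
      exp(-(dx^2 + dy^2) / (2 * spec$thickness_bump_sigma^2))
  }
  thickness_fn <- function(x, y) 2 * off + bump(x, y)

  # --- static bead skeleton -------------------------------------------------
  lipid_beads <- function(df, side) { # side: +1 outer, -1 inner
    if (is.null(df)) return(NULL)
    rows <- lapply(seq_len(nrow(df)), function(i) {
      r <- df$residue[i]
      ei <- match(r, e$residue)
      hg <- e$headgroup[ei]
      if (hg == "CHOL") {
        b <- c("ROH", "R1"); dz <- c(0.25, 0.6)
      } else if (hg %in% c("GM", "CER", "DAG")) {
        b <- "AM1"; dz <- 0  # no phosphate bead for glycolipids/ceramides
      } else {
        b <- "PO4"; dz <- 0
      }
      if (!is.na(e$tail1[ei])) { b <- c(b, "C1A", "C2A"); dz <- c(dz, 0.35, 0.7) }
      if (!is.na(e$tail2[ei])) { b <- c(b, "C1B", "C2B"); dz <- c(dz, 0.35, 0.7) }
      data.frame(x = df$x[i], y = df$y[i], dz = dz, bead = b,
                 residue = r, lip = i, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$side <- side
    out
  }
  bi <- lipid_beads(inner, -1L)
  bo <- lipid_beads(outer_, +1L)
  skel <- rbind(bi, bo)
  if (is.null(skel) || !nrow(skel)) stop("composition yields no lipids")
  skel$resid <- cumsum(!duplicated(paste(skel$side, skel$lip)))
  n_lip_res <- max(skel$resid)

  np_bead_offsets <- if (spec$np_bead_expansion) {
    k <- 16L
    gr <- (1 + sqrt(5)) / 2
    i <- seq_len(k) - 0.5
    phi <- acos(1 - 2 * i / k); theta <- 2 * pi * i / gr
    0.25 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  } else matrix(0, 1, 3)

  # --- per-frame realization ------------------------------------------------
  make_frame <- function(fidx) {
    jx <- stats::rnorm(nrow(skel), 0, 0.08) * (skel$bead %in%
            c("C1A", "C2A", "C1B", "C2B", "R1"))
    jy <- stats::rnorm(nrow(skel), 0, 0.08) * (skel$bead %in%
            c("C1A", "C2A", "C1B", "C2B", "R1"))
    x <- skel$x + jx; y <- skel$y + jy
    surf <- midplane(skel$x, skel$y) +
      skel$side * (off + bump(skel$x, skel$y) / 2)
    z <- surf - skel$side * skel$dz
    pos <- cbind(x, y, z)
    resname <- skel$residue
    bead <- skel$bead
    resid <- skel$resid

    np_xy <- NULL; np_res <- integer(0); clustered <- logical(0)
    if (np > 0L) {
      n_disp <- np - n_clustered
      xy_d <- draw_np_xy(n_disp)
      xy_c <- matrix(numeric(0), 0, 2)
      if (n_clustered > 0L) {
        xy_c <- matrix(0, n_clustered, 2)
        zc <- numeric(n_clustered)
        xy_c[1, ] <- cluster_center
        zc[1] <- 0
        if (n_clustered > 1L) for (j in 2:n_clustered) {
          anchor <- sample.int(j - 1L, 1L)
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)) * 0.55
          xy_c[j, ] <- xy_c[anchor, ] + u[1:2]
          zc[j] <- max(-0.9, min(0.9, zc[anchor] + u[3]))
        }
      }
      np_xy <- rbind(xy_c, xy_d)
      clustered <- c(rep(TRUE, n_clustered), rep(FALSE, np - n_clustered))
      np_z <- midplane(np_xy[, 1], np_xy[, 2]) +
        c(if (n_clustered) zc, stats::rnorm(np - n_clustered, 0, 0.25))
      np_res <- n_lip_res + seq_len(np)
      nb <- nrow(np_bead_offsets)
      np_pos <- matrix(0, np * nb, 3)
      for (m in seq_len(np)) {
        base <- c(np_xy[m, 1], np_xy[m, 2], np_z[m])
        np_pos[(m - 1L) * nb + seq_len(nb), ] <-
          sweep(np_bead_offsets, 2, base, `+`)
      }
      pos <- rbind(pos, np_pos)
      resname <- c(resname, rep("C60", np * nb))
      bead <- c(bead, rep(sprintf("F%d", seq_len(nb)), np))
      resid <- c(resid, rep(np_res, each = nb))
    }
    list(fr = frame(pos, resname, bead, resid, spec$box,
                    time = (fidx - 1L) * 1000),
         clustered = clustered)
  }

  frames <- vector("list", n_frames)
  clustered <- logical(0)
  for (f in seq_len(n_frames)) {
    mk <- make_frame(f)
    frames[[f]] <- mk$fr
    if (f == 1L) clustered <- mk$clustered
  }
  traj <- trajectory(frames, composition = comp)

  fr1 <- frames[[1]]
  leaflet_bead <- character(nrow(fr1$positions))
  leaflet_bead[fr1$resid <= n_lip_res] <-
    ifelse(skel$side[match(fr1$resid[fr1$resid <= n_lip_res], skel$resid)] > 0,
           "outer", "inner")
  leaflet_bead[fr1$resid > n_lip_res] <- "np"
  lip_leaflet <- vapply(split(leaflet_bead[fr1$resid <= n_lip_res],
                              fr1$resid[fr1$resid <= n_lip_res]),
                        `[`, character(1), 1L)

  truth <- list(
    leaflet_bead = leaflet_bead,
    leaflet_lipid = data.frame(resid = as.integer(names(lip_leaflet)),
                               leaflet = unname(lip_leaflet),
                               stringsAsFactors = FALSE),
    target = target,
    strength = spec$np_colocal_strength,
    np_resids = if (np > 0L) n_lip_res + seq_len(np) else integer(0),
    cluster_members = if (np > 0L) (n_lip_res + seq_len(np))[clustered]
                      else integer(0),
    patch_field = field, patch_threshold = thr,
    midplane = midplane,
    undulation_modes = und,
    thickness = thickness_fn,
    spec = spec)
  list(trajectory = traj, truth = truth)
}

#' Draw umbrella-sampling windows from a known potential
#'
#' For each bias center c, draws samples from the density proportional to
#' \code{exp(-(U(z) + k/2 (z - c)^2) / kT)} by random-walk Metropolis with
#' 10x thinning after a 10\% burn-in, so the output emulates an
#' umbrella-sampling run along the membrane normal with an analytically known
#' unbiased potential.
#'
#' @param true_potential either a vectorized function \code{U(z)} returning
#'   kJ/mol, or a two-column matrix/data.frame of (z, U) tabulating it
#'   (linear interpolation; outside the tabulated range the density is 0).
#' @param centers bias centers (nm), strictly increasing.
#' @param force_const harmonic force constant k (kJ mol^-1 nm^-2).
#' @param n_samples samples kept per window (>= 100).
#' @param temperature K.
#' @param seed integer seed; sampling is deterministic under it.
#' @param thin keep every \code{thin}-th Metropolis step (default 10).
#' @return list of \code{umbrella_window} objects (fields \code{center},
#'   \code{force_const}, \code{samples}, \code{n_samples}).
#' @export
sample_umbrella_windows <- function(true_potential, centers, force_const,
                                    n_samples, temperature = 298,
                                    seed = 1L, thin = 10L) {
  if (is.unsorted(centers, strictly = TRUE))
    stop("centers must be strictly increasing")
  if (force_const <= 0) stop("force_const must be > 0")
  if (n_samples < 100) stop("n_samples must be >= 100")
  U <- as_potential(true_potential)
  if (!all(is.finite(U(centers))))
    stop("potential is not finite at all bias centers; ",
         "biased density would not be normalizable on the support")
  kt <- kT(temperature)
  with_seed(seed, {
    nw <- length(centers)
    n_chains <- max(1L, ceiling(n_samples / 500))
    n_keep <- ceiling(n_samples / n_chains)
    n_main <- n_keep * thin
    n_burn <- ceiling(0.1 * n_main)
    walk_c <- rep(centers, each = n_chains)   # per-walker bias center
    nwalk <- length(walk_c)
    sigma <- sqrt(kt / force_const)
    step <- 2.4 * sigma
    z <- walk_c + stats::rnorm(nwalk, 0, sigma)
    logp <- function(zz, cc) {
      u <- U(zz)
      ifelse(is.finite(u), -(u + 0.5 * force_const * (zz - cc)^2) / kt, -Inf)
    }
    lp <- logp(z, walk_c)
    bad <- !is.finite(lp)
    if (any(bad)) { z[bad] <- walk_c[bad]; lp <- logp(z, walk_c) }
    kept <- matrix(0, n_keep, nwalk)
    ki <- 0L
    for (it in seq_len(n_burn + n_main)) {
      zp <- z + stats::rnorm(nwalk, 0, step)
      lpp <- logp(zp, walk_c)
      acc <- log(stats::runif(nwalk)) < (lpp - lp)
      z[acc] <- zp[acc]; lp[acc] <- lpp[acc]
      if (it > n_burn && (it - n_burn) %% thin == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- z
      }
    }
    lapply(seq_len(nw), function(i) {
      cols <- (i - 1L) * n_chains + seq_len(n_chains)
      s <- as.vector(kept[, cols])[seq_len(n_samples)]
      umbrella_window(centers[i], force_const, s)
    })
  })
}

# Normalize a potential spec to a vectorized function.
as_potential <- function(U) {
  if (is.function(U)) return(U)
  tab <- as.matrix(U)
  if (ncol(tab) != 2L) stop("tabulated potential must have two columns (z, U)")
  if (is.unsorted(tab[, 1], strictly = TRUE))
    stop("tabulated potential z values must be strictly increasing")
  f <- stats::approxfun(tab[, 1], tab[, 2], rule = 1)
  function(z) {
    u <- f(z)
    u[is.na(u)] <- Inf
    u
  }
}
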