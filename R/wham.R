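#' Umbrella-sampling window
#'
#' One biased-sampling record: harmonic bias center and force constant along
#' the membrane normal, and the sampled reaction-coordinate values.
#'
#' @param center bias center (nm).
#' @param force_const harmonic force constant (kJ mol^-1 nm^-2), > 0.
#' @param samples numeric vector of sampled z values (nm).
#' @return an object of class \code{umbrella_window}.
#' @export
umbrella_window <- function(center, force_const, samples) {
  if (force_const <= 0) stop("force_const must be > 0")
  samples <- as.numeric(samples)
  if (!length(samples) || !all(is.finite(samples)))
    stop("samples must be non-empty and finite")
  structure(list(center = as.numeric(center),
                 force_const = as.numeric(force_const),
                 samples = samples, n_samples = length(samples)),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat("<umbrella_window> center", x$center, "nm, k", x$force_const,
      "kJ/mol/nm^2,", x$n_samples, "samples\n")
  invisible(x)
}

#' Write / read umbrella windows as delimited text
#'
#' One file per window: two comment header lines carrying the bias center
#' and force constant, then one sample per line. A manifest file (one window
#' path per line, relative to the manifest's directory) ties a set of
#' windows together.
#'
#' @param windows list of [umbrella_window].
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within \code{dir}.
#' @return path to the manifest, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, manifest = "windows.txt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    files[i] <- sprintf("window_%03d.dat", i)
    writeLines(c(sprintf("# center: %.10g", w$center),
                 sprintf("# force_const: %.10g", w$force_const),
                 format(w$samples, digits = 10, trim = TRUE, scientific = FALSE)),
               file.path(dir, files[i]))
  }
  writeLines(files, file.path(dir, manifest))
  invisible(file.path(dir, manifest))
}

#' @rdname write_umbrella_windows
#' @param path manifest path (for \code{read_umbrella_windows}) or a single
#'   window file (for \code{read_umbrella_window}).
#' @export
read_umbrella_windows <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  files <- readLines(path)
  files <- files[nzchar(trimws(files))]
  lapply(file.path(dirname(path), files), read_umbrella_window)
}

#' @rdname write_umbrella_windows
#' @export
read_umbrella_window <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
    if (!length(m)) stop("window file ", path, " lacks '# ", key, ":' header")
    as.numeric(sub(paste0("^#\\s*", key, ":?\\s*"), "", m[1]))
  }
  smp <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  umbrella_window(getv("center"), getv("force_const"), smp)
}

# Shared histogram + bias machinery for a window set on fixed bin edges.
wham_setup <- function(windows, bin_width, bin_edges = NULL) {
  rng <- range(unlist(lapply(windows, `[[`, "samples")))
  if (is.null(bin_edges)) {
    lo <- floor(rng[1] / bin_width) * bin_width
    hi <- ceiling(rng[2] / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    bin_edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  mids <- bin_edges[-length(bin_edges)] + diff(bin_edges) / 2
  nb <- length(mids); nw <- length(windows)
  counts <- matrix(0, nb, nw)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    b <- pmin(pmax(findInterval(s, bin_edges, all.inside = TRUE), 1L), nb)
    counts[, i] <- tabulate(b, nbins = nb)
  }
  list(edges = bin_edges, mids = mids, counts = counts)
}

#' Solve WHAM for a 1D potential of mean force
#'
#' Standard self-consistent weighted histogram analysis: with per-window
#' histograms n_i(z), sample counts N_i and bias potentials
#' U_i(z) = k_i/2 (z - c_i)^2, iterate
#' \deqn{P(z) = \frac{\sum_i n_i(z)}{\sum_i N_i \exp[(f_i - U_i(z))/k_BT]},
#'   \quad f_i = -k_BT \ln \sum_z P(z) \exp[-U_i(z)/k_BT]}
#' until the window free energies f_i stop changing, then
#' G(z) = -k_BT ln P(z), shifted so the mean over the reference region is 0.
#' Bins with zero total counts are masked (\code{NA}).
#'
#' The default reference region is the outermost 0.5 nm of coverage at the
#' high-z end — the bulk-water side when the reaction coordinate is distance
#' from the bilayer center — matching the convention that the PMF is zero in
#' water.
#'
#' @param windows list of [umbrella_window].
#' @param bin_width nm, default 0.05.
#' @param temperature K, default 298.
#' @param tol relative convergence tolerance on the f_i (default 1e-7).
#' @param max_iter maximum iterations (default 1e5).
#' @param reference_region length-2 numeric (z range with G = 0), or
#'   \code{NULL} for the default.
#' @param bin_edges optional fixed bin edges (used by the bootstrap so all
#'   replicates share bins).
#' @param f_init optional starting values for the window free energies
#'   (warm start; the fixed point does not depend on it).
#' @return a \code{pmf_profile}: data.frame with columns \code{z},
#'   \code{G} (kJ/mol), \code{se} (NA here; filled by [bootstrap_pmf]);
#'   attributes \code{temperature}, \code{iterations}, \code{residual},
#'   \code{reference_region}, \code{f} (window free energies),
#'   \code{bin_edges}.
#' @export
wham_solve <- function(windows, bin_width = 0.05, temperature = 298,
                       tol = 1e-7, max_iter = 1e5,
                       reference_region = NULL, bin_edges = NULL,
                       f_init = NULL) {
  if (!length(windows)) stop("need at least one window")
  stopifnot(all(vapply(windows, inherits, logical(1), "umbrella_window")))
  if (temperature <= 0) stop("temperature must be > 0")
  kt <- kT(temperature)
  su <- wham_setup(windows, bin_width, bin_edges)
  nb <- length(su$mids); nw <- length(windows)
  Ni <- vapply(windows, `[[`, numeric(1), "n_samples")
  cen <- vapply(windows, `[[`, numeric(1), "center")
  kk <- vapply(windows, `[[`, numeric(1), "force_const")
  # bias Boltzmann factors, nb x nw (underflows cleanly to 0 for far bins)
  B <- exp(-outer(su$mids, seq_len(nw),
                  function(z, i) 0.5 * kk[i] * (z - cen[i])^2) / kt)

  # overlap warning between adjacent windows (sorted by center)
  ordw <- order(cen)
  for (j in seq_len(nw - 1L)) {
    a <- su$counts[, ordw[j]] > 0; b <- su$counts[, ordw[j + 1L]] > 0
    if (!any(a & b))
      warning("windows at centers ", cen[ordw[j]], " and ",
              cen[ordw[j + 1L]], " share no occupied bins; ",
              "profile may be disconnected")
  }

  ntot <- rowSums(su$counts)
  f <- if (!is.null(f_init) && length(f_init) == nw) f_init - f_init[1]
       else numeric(nw)
  resid <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- B %*% (Ni * exp(f / kt))
    P <- ifelse(ntot > 0, ntot / pmax(denom, .Machine$double.xmin), 0)
    P <- P / sum(P)
    fnew <- -kt * log(pmax(colSums(P * B), .Machine$double.xmin))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f) / pmax(abs(fnew), 1))
    f <- fnew
    if (resid < tol || it >= max_iter) break
  }
  if (resid >= tol)
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", format(resid, digits = 3), ")")
  G <- ifelse(ntot > 0, -kt * log(P), NA_real_)
  covered <- which(ntot > 0)
  if (is.null(reference_region)) {
    zmax <- su$mids[max(covered)]
    reference_region <- c(zmax - 0.5, zmax)
  }
  refbins <- which(!is.na(G) & su$mids >= reference_region[1] &
                     su$mids <= reference_region[2])
  if (!length(refbins)) stop("reference region contains no covered bins")
  G <- G - mean(G[refbins])
  out <- data.frame(z = su$mids, G = G, se = NA_real_)
  attr(out, "temperature") <- temperature
  attr(out, "iterations") <- it
  attr(out, "residual") <- resid
  attr(out, "reference_region") <- reference_region
  attr(out, "f") <- f
  attr(out, "bin_edges") <- su$edges
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' @export
print.pmf_profile <- function(x, ...) {
  cov <- !is.na(x$G)
  cat("<pmf_profile>", sum(cov), "covered bins over z in [",
      sprintf("%.2f, %.2f", min(x$z[cov]), max(x$z[cov])), "] nm, T =",
      attr(x, "temperature"), "K,", attr(x, "iterations"), "iterations\n")
  mn <- pmf_minimum(x)
  cat(sprintf("  minimum %.2f kJ/mol at z = %.3f nm%s\n", mn$depth,
              mn$position, if (mn$boundary) " (boundary minimum)" else ""))
  invisible(x)
}

#' Bootstrap confidence band for a WHAM profile
#'
#' Ordinary within-window bootstrap: each replicate resamples every window's
#' samples with replacement, re-solves WHAM on the original bins, and the
#' per-bin standard error is the standard deviation of G across replicates.
#' Deterministic under a fixed seed.
#'
#' @inheritParams wham_solve
#' @param n_boot number of replicates (>= 20).
#' @param seed integer seed.
#' @param block_length optional block length for a moving-block bootstrap of
#'   correlated samples; \code{NULL} (default) resamples single values.
#' @return a \code{pmf_profile} with the \code{se} column filled; attribute
#'   \code{n_boot}.
#' @export
bootstrap_pmf <- function(windows, n_boot = 100, seed = 1L,
                          bin_width = 0.05, temperature = 298,
                          tol = 1e-7, max_iter = 1e5,
                          reference_region = NULL, block_length = NULL) {
  if (n_boot < 20) stop("n_boot must be >= 20")
  base <- wham_solve(windows, bin_width, temperature, tol, max_iter,
                     reference_region)
  edges <- attr(base, "bin_edges")
  refreg <- attr(base, "reference_region")
  Gmat <- with_seed(seed, {
    g <- vapply(seq_len(n_boot), function(b) {
      wb <- lapply(windows, function(w) {
        s <- if (is.null(block_length)) {
          w$samples[sample.int(w$n_samples, w$n_samples, replace = TRUE)]
        } else {
          L <- max(1L, as.integer(block_length))
          nblk <- ceiling(w$n_samples / L)
          starts <- sample.int(max(1L, w$n_samples - L + 1L), nblk,
                               replace = TRUE)
          idx <- as.vector(outer(0:(L - 1L), starts, `+`))
          w$samples[idx[seq_len(w$n_samples)]]
        }
        umbrella_window(w$center, w$force_const, s)
      })
      suppressWarnings(
        wham_solve(wb, bin_width, temperature, tol, max_iter,
                   reference_region = refreg, bin_edges = edges,
                   f_init = attr(base, "f"))$G)
    }, numeric(nrow(base)))
    matrix(g, nrow = nrow(base))  # guard the single-bin case
  })
  base$se <- apply(Gmat, 1, stats::sd, na.rm = TRUE)
  base$se[is.na(base$G)] <- NA_real_
  attr(base, "n_boot") <- n_boot
  base
}

#' Locate the free-energy minimum of a PMF
#'
#' Returns the global minimum over covered bins, relative to the profile's
#' zero reference, with an optional quadratic sub-bin refinement. A minimum
#' at the first or last covered bin is flagged as a boundary minimum.
#'
#' @param profile a \code{pmf_profile}.
#' @param refine quadratic interpolation through the minimum and its
#'   neighbours (default FALSE).
#' @return list with \code{depth} (kJ/mol), \code{position} (nm) and
#'   \code{boundary} (logical).
#' @export
pmf_minimum <- function(profile, refine = FALSE) {
  stopifnot(inherits(profile, "pmf_profile"))
  cov <- which(!is.na(profile$G))
  if (!length(cov)) stop("profile has no covered bins")
  i <- cov[which.min(profile$G[cov])]
  boundary <- i == cov[1] || i == cov[length(cov)]
  depth <- profile$G[i]; pos <- profile$z[i]
  if (refine && !boundary &&
      all(c(i - 1L, i + 1L) %in% cov)) {
    z3 <- profile$z[(i - 1L):(i + 1L)]
    g3 <- profile$G[(i - 1L):(i + 1L)]
    co <- solve(cbind(1, z3, z3^2), g3)
    if (co[3] > 0) {
      pos <- -co[2] / (2 * co[3])
      depth <- co[1] + co[2] * pos + co[3] * pos^2
    }
  }
  list(depth = depth, position = pos, boundary = boundary)
}
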