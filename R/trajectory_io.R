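#' Coordinate frame
#'
#' One simulation snapshot: bead positions in nm, per-bead species labels,
#' residue indices and an orthorhombic box. Coordinates are wrapped into
#' \code{[0, box)} on construction so gridded analyses can assume in-box
#' positions.
#'
#' @param positions numeric matrix, n x 3, nm.
#' @param resname character vector of residue names, length n.
#' @param bead character vector of bead names, length n.
#' @param resid integer vector of residue indices, length n.
#' @param box numeric length-3 vector of box lengths, nm.
#' @param time time in ps, or \code{NA}.
#' @param wrap wrap coordinates into the box (default \code{TRUE}).
#' @return an object of class \code{frame} with fields \code{positions},
#'   \code{resname}, \code{bead}, \code{species} (\code{"RESNAME:BEADNAME"}),
#'   \code{resid}, \code{box}, \code{time}.
#' @export
frame <- function(positions, resname, bead, resid, box, time = NA_real_,
                  wrap = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  if (length(resname) != n || length(bead) != n || length(resid) != n)
    stop("positions, resname, bead and resid must have equal length")
  if (!all(is.finite(positions))) stop("non-finite coordinates in frame")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || !all(box > 0))
    stop("box must be three positive finite lengths (nm)")
  if (wrap) positions <- wrap_positions(positions, box)
  structure(list(positions = positions,
                 resname = as.character(resname),
                 bead = as.character(bead),
                 species = paste(resname, bead, sep = ":"),
                 resid = as.integer(resid),
                 box = box,
                 time = as.numeric(time)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("<frame>", nrow(x$positions), "beads,",
      length(unique(x$resid)), "residues, box",
      paste(sprintf("%.2f", x$box), collapse = " x "), "nm")
  if (!is.na(x$time)) cat(", t =", x$time, "ps")
  cat("\n")
  invisible(x)
}

#' Trajectory
#'
#' An ordered sequence of [frame] objects sharing bead count and species
#' ordering, optionally carrying the system's [composition].
#'
#' @param frames list of [frame] objects.
#' @param composition optional [composition].
#' @return an object of class \code{trajectory}.
#' @export
trajectory <- function(frames, composition = NULL) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "frame")))
    stop("all elements must be frame objects")
  sp0 <- frames[[1]]$species
  for (i in seq_along(frames)) {
    if (!identical(frames[[i]]$species, sp0))
      stop("frame ", i, " differs in bead count or species ordering")
  }
  tm <- vapply(frames, `[[`, numeric(1), "time")
  if (all(!is.na(tm)) && is.unsorted(tm))
    stop("frame times must be non-decreasing")
  if (!is.null(composition)) {
    stopifnot(inherits(composition, "composition"))
    check_composition_coverage(composition, frames[[1]])
  }
  structure(list(frames = frames, composition = composition),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frame(s),",
      nrow(x$frames[[1]]$positions), "beads")
  if (!is.null(x$composition))
    cat(",", nrow(x$composition$entries), "composition entries")
  cat("\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Read coordinate frames
#'
#' Reads a (possibly multi-frame) GRO file or a (possibly multi-model) PDB
#' file into a [trajectory]. GRO coordinates are in nm; PDB coordinates are
#' in Angstrom and converted to nm (including the CRYST1 box). Only
#' orthorhombic boxes are supported; a triclinic box record is an error.
#' Coordinates are wrapped into the box on read.
#'
#' @param path file path.
#' @param format \code{"gro"} or \code{"pdb"}; default guesses from the
#'   file extension.
#' @param composition optional [composition] attached to the trajectory.
#' @return a [trajectory].
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb"),
                        composition = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format="))
  }
  frames <- switch(format, gro = read_gro(path), pdb = read_pdb_frames(path))
  trajectory(frames, composition = composition)
}

# -- GRO ---------------------------------------------------------------------

# Hand-written fixed-column GRO reader (multi-frame files are concatenated
# title/natoms/atoms/box blocks). Velocities, if present, are ignored.
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 0)
      stop("GRO parse error at line ", i + 1L, ": expected atom count")
    if (i + 1L + natoms > length(lines))
      stop("GRO parse error: truncated frame starting at line ", i)
    if (i + 1L + natoms + 1L > length(lines))
      stop("GRO parse error at line ", i + 1L + natoms + 1L,
           ": missing box record (box is required)")
    at <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- suppressWarnings(as.integer(substr(at, 1L, 5L)))
    resname <- trimws(substr(at, 6L, 10L))
    bead <- trimws(substr(at, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(at, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(at, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(at, 37L, 44L)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop("GRO parse error at line ", i + 1L + bad[1L],
           ": malformed atom record")
    boxline <- trimws(lines[i + 1L + natoms + 1L])
    if (!nzchar(boxline))
      stop("GRO parse error at line ", i + 1L + natoms + 1L,
           ": missing box record (box is required)")
    bv <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1L]]))
    if (anyNA(bv)) stop("GRO parse error at line ", i + 1L + natoms + 1L,
                        ": malformed box record")
    if (length(bv) > 3L && any(bv[-(1:3)] != 0))
      stop("triclinic box at line ", i + 1L + natoms + 1L,
           " is unsupported (orthorhombic boxes only)")
    tm <- NA_real_
    mt <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(mt)) tm <- as.numeric(sub("t=\\s*", "", mt))
    frames[[length(frames) + 1L]] <-
      frame(cbind(x, y, z), resname, bead, resid, bv[1:3], time = tm)
    i <- i + 1L + natoms + 2L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write a trajectory to a GRO file
#'
#' Positions are written with the format's 3-decimal precision in nm, so a
#' read/write round trip reproduces coordinates to within 0.0005 nm.
#'
#' @param traj a [trajectory] (or single [frame]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_frames <- function(traj, path) {
  if (inherits(traj, "frame")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"))
  if (!length(traj$frames)) stop("empty trajectory: nothing to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    n <- nrow(fr$positions)
    title <- if (is.na(fr$time)) "memshadow frame"
             else sprintf("memshadow frame t= %g", fr$time)
    writeLines(c(title, sprintf("%5d", n)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       fr$resid %% 100000L, fr$resname, fr$bead,
                       seq_len(n) %% 100000L,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
    writeLines(sprintf("%.5f %.5f %.5f",
                       fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

# -- PDB (via bio3d) ---------------------------------------------------------

read_pdb_frames <- function(path) {
  # box from the CRYST1 record (fixed columns per the PDB standard)
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cl))
    stop("PDB file lacks a CRYST1 box record (box is required)")
  fld <- function(l, a, b) suppressWarnings(as.numeric(substr(l, a, b)))
  abc <- c(fld(cl[1], 7, 15), fld(cl[1], 16, 24), fld(cl[1], 25, 33))
  ang <- c(fld(cl[1], 34, 40), fld(cl[1], 41, 47), fld(cl[1], 48, 54))
  if (anyNA(abc)) stop("malformed CRYST1 record in ", path)
  if (any(abs(ang - 90) > 1e-6, na.rm = TRUE))
    stop("triclinic box (CRYST1 angles != 90) is unsupported")
  box <- abc / 10  # Angstrom -> nm
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  resname <- trimws(pdb$atom$resid)
  bead <- trimws(pdb$atom$elety)
  resid <- pdb$atom$resno
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(k) {
    pos <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE) / 10
    frame(pos, resname, bead, resid, box)
  })
}
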