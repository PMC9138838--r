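#' Bead selectors
#'
#' Analyses select beads by residue name and/or bead name. A selector is a
#' small object holding one or more (residues, bead-pattern) groups; a bead
#' matches the selector if it matches any group. Bead patterns are regular
#' expressions on the bead name (the part after the colon in the per-bead
#' species label \code{"RESNAME:BEADNAME"}).
#'
#' @param residues character vector of residue names, or \code{NULL} for any.
#' @param beads regular expression on bead names, or \code{NULL} for any.
#' @param label display label for the selector.
#' @return an object of class \code{species_selector}.
#' @examples
#' species_selector(residues = "C60", label = "NP")
#' species_selector(beads = "^PO4$", label = "phosphates")
#' @export
species_selector <- function(residues = NULL, beads = NULL,
                             label = NULL) {
  if (is.null(label)) {
    label <- if (!is.null(residues)) paste(residues, collapse = "+")
             else beads %||% "all"
  }
  structure(list(groups = list(list(residues = residues, beads = beads)),
                 label = label),
            class = "species_selector")
}

# Combine selector groups (union of matches).
selector_union <- function(..., label) {
  sels <- list(...)
  structure(list(groups = do.call(c, lapply(sels, `[[`, "groups")),
                 label = label),
            class = "species_selector")
}

#' @export
print.species_selector <- function(x, ...) {
  cat("<species_selector>", x$label, "-", length(x$groups), "group(s)\n")
  invisible(x)
}

# Martini-style tail bead names: C1A/D2A... for tail 1, C1B/D2B... for tail 2.
.TAIL1_RE <- "^[A-Z][0-9]+A$"
.TAIL2_RE <- "^[A-Z][0-9]+B$"

#' Selector for all beads of one lipid-tail type
#'
#' Resolves a two-letter tail code (e.g. \code{"DA"}) against a composition
#' table: residues whose first tail carries the code contribute their tail-1
#' beads, residues whose second tail carries it contribute their tail-2 beads.
#' Headgroup, phosphate and glycerol beads are excluded, matching the
#' convention that tail co-localization is measured on acyl-chain beads only.
#'
#' @param composition a [composition] object.
#' @param tail_code two-letter tail code present in the composition.
#' @return a \code{species_selector}.
#' @export
tail_selector <- function(composition, tail_code) {
  stopifnot(inherits(composition, "composition"))
  e <- composition$entries
  r1 <- e$residue[!is.na(e$tail1) & e$tail1 == tail_code]
  r2 <- e$residue[!is.na(e$tail2) & e$tail2 == tail_code]
  if (!length(r1) && !length(r2))
    stop("tail code '", tail_code, "' not present in composition")
  groups <- list()
  if (length(r1)) groups <- c(groups, list(list(residues = r1, beads = .TAIL1_RE)))
  if (length(r2)) groups <- c(groups, list(list(residues = r2, beads = .TAIL2_RE)))
  structure(list(groups = groups, label = tail_code),
            class = "species_selector")
}

#' Selector for sterol beads
#' @param composition a [composition] object.
#' @return a \code{species_selector} matching all beads of residues whose
#'   headgroup class is \code{CHOL}.
#' @export
sterol_selector <- function(composition) {
  e <- composition$entries
  r <- e$residue[e$headgroup == "CHOL"]
  if (!length(r)) stop("composition contains no sterol (headgroup CHOL)")
  species_selector(residues = r, label = "CHOL")
}

#' Selector for nanoparticle beads
#' @param composition a [composition] object.
#' @param resname nanoparticle residue name; default: residues with
#'   headgroup class \code{NP} in the composition, falling back to "C60".
#' @return a \code{species_selector}.
#' @export
np_selector <- function(composition = NULL, resname = NULL) {
  if (is.null(resname)) {
    resname <- "C60"
    if (!is.null(composition)) {
      r <- composition$entries$residue[composition$entries$headgroup == "NP"]
      if (length(r)) resname <- r
    }
  }
  species_selector(residues = resname, label = paste(resname, collapse = "+"))
}

# Logical index of beads in `frame` matched by `selector`.
match_beads <- function(frame, selector) {
  stopifnot(inherits(selector, "species_selector"))
  res <- frame$resname
  bead <- frame$bead
  hit <- rep(FALSE, length(res))
  for (g in selector$groups) {
    m <- rep(TRUE, length(res))
    if (!is.null(g$residues)) m <- m & res %in% g$residues
    if (!is.null(g$beads)) m <- m & grepl(g$beads, bead)
    hit <- hit | m
  }
  hit
}

# match_beads that errors (naming the selector) when nothing matches.
match_beads_strict <- function(frame, selector) {
  hit <- match_beads(frame, selector)
  if (!any(hit))
    stop("selector '", selector$label, "' matches no beads in frame")
  hit
}
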