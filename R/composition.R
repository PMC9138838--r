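#' Lipid composition table
#'
#' Species metadata for a membrane system: one row per residue name, with
#' headgroup class, tail codes, per-tail double-bond counts, leaflet and
#' molecule count. Residues with no tails (sterols, nanoparticles) leave the
#' tail columns empty.
#'
#' @param entries data.frame with columns \code{residue}, \code{headgroup},
#'   \code{tail1}, \code{tail2}, \code{db1}, \code{db2}, \code{leaflet},
#'   \code{count}.
#' @return an object of class \code{composition}.
#' @export
composition <- function(entries) {
  req <- c("residue", "headgroup", "tail1", "tail2", "db1", "db2",
           "leaflet", "count")
  if (!all(req %in% names(entries)))
    stop("composition requires columns: ", paste(req, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$residue <- as.character(entries$residue)
  entries$headgroup <- toupper(as.character(entries$headgroup))
  for (cc in c("tail1", "tail2")) {
    v <- as.character(entries[[cc]])
    v[!nzchar(trimws(v)) | is.na(v)] <- NA_character_
    entries[[cc]] <- v
  }
  entries$db1 <- as.integer(entries$db1)
  entries$db2 <- as.integer(entries$db2)
  entries$leaflet <- tolower(as.character(entries$leaflet))
  entries$count <- as.integer(entries$count)
  if (anyDuplicated(entries$residue))
    stop("duplicate residue name(s) in composition: ",
         paste(unique(entries$residue[duplicated(entries$residue)]),
               collapse = ", "))
  hg_ok <- c("PC", "PE", "SM", "PS", "PIP", "GM", "CER", "DAG", "LPC",
             "PA", "PI", "CHOL", "NP")
  bad <- setdiff(unique(entries$headgroup), hg_ok)
  if (length(bad))
    stop("unknown headgroup class(es): ", paste(bad, collapse = ", "))
  if (any(is.na(entries$count)) || any(entries$count < 0))
    stop("counts must be non-negative integers")
  db <- c(entries$db1[!is.na(entries$tail1)], entries$db2[!is.na(entries$tail2)])
  if (any(is.na(db)) || any(db < 0) || any(db > 6))
    stop("double-bond counts must be integers in 0..6")
  lf_ok <- c("inner", "outer", "both", "n/a")
  if (!all(entries$leaflet %in% lf_ok))
    stop("leaflet must be one of: ", paste(lf_ok, collapse = ", "))
  structure(list(entries = entries), class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  e <- x$entries
  cat("<composition>", nrow(e), "species,",
      sum(e$count[e$headgroup != "NP"]), "lipids",
      sprintf("(%.1f mol%% sterol)\n",
              100 * sum(e$count[e$headgroup == "CHOL"]) /
                max(1L, sum(e$count[e$headgroup != "NP"]))))
  print(utils::head(e, 10))
  if (nrow(e) > 10) cat("...", nrow(e) - 10, "more rows\n")
  invisible(x)
}

#' Read a composition table from CSV
#'
#' Expects a delimited text file with header columns \code{residue},
#' \code{headgroup}, \code{tail1}, \code{tail2}, \code{db1}, \code{db2},
#' \code{leaflet}, \code{count}. Duplicate residue names and negative counts
#' are errors.
#'
#' @param path CSV file path.
#' @return a [composition].
#' @export
read_composition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  df$db1[!nzchar(df$db1)] <- "0"
  df$db2[!nzchar(df$db2)] <- "0"
  composition(df)
}

# Every residue in the frame that is not water/ion/nanoparticle must have a
# composition entry (Frame invariant).
check_composition_coverage <- function(comp, fr) {
  skip <- c("W", "WN", "NA", "NA+", "CL", "CL-", "ION")
  res <- setdiff(unique(fr$resname), skip)
  np <- comp$entries$residue[comp$entries$headgroup == "NP"]
  res <- setdiff(res, c(np, "C60"))
  missing <- setdiff(res, comp$entries$residue)
  if (length(missing))
    stop("residues present in frame but absent from composition: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# Per-leaflet integer lipid counts by residue; leaflet "both" is split evenly
# (inner gets the floor). Nanoparticle entries are excluded.
leaflet_counts <- function(comp) {
  e <- comp$entries[comp$entries$headgroup != "NP", , drop = FALSE]
  inner <- outer <- integer(0)
  for (i in seq_len(nrow(e))) {
    r <- e$residue[i]; n <- e$count[i]
    switch(e$leaflet[i],
      inner = { inner[r] <- n },
      outer = { outer[r] <- n },
      both = { inner[r] <- n %/% 2L; outer[r] <- n - n %/% 2L },
      "n/a" = {})
  }
  list(inner = inner[inner > 0], outer = outer[outer > 0])
}
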