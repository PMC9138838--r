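#' Run an end-to-end analysis pipeline
#'
#' Orchestrates generate (or load) -> analyze -> report from a single config,
#' writing every result as CSV plus a JSON manifest recording inputs,
#' parameters, package version and seed. Re-running with the same config and
#' seed reproduces all CSV outputs bit-identically.
#'
#' The config is a YAML file or an equivalent nested list with blocks:
#' \describe{
#'   \item{seed}{integer, used for every stochastic stage.}
#'   \item{outdir}{output directory.}
#'   \item{membrane}{[membrane_spec] arguments plus \code{composition} (CSV
#'     path; omit for the bundled plasma-membrane table) and
#'     \code{n_frames} — generates a synthetic system; mutually exclusive
#'     with \code{input}.}
#'   \item{input}{\code{trajectory} (GRO/PDB path) and \code{composition}
#'     (CSV path) — analyze an existing system.}
#'   \item{analyses}{any of \code{colocal}, \code{density},
#'     \code{enrichment}, \code{thickness}, \code{undulation},
#'     \code{clusters}, \code{unsat}, each a (possibly empty) list of
#'     stage parameters.}
#'   \item{wham}{\code{windows} (manifest path) plus \code{bin_width},
#'     \code{temperature}, \code{n_boot}.}
#' }
#'
#' @param config YAML file path or a nested list.
#' @param outdir overrides the config's output directory.
#' @return the manifest, invisibly (list; also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  outdir <- outdir %||% config$outdir %||% stop("config needs an outdir")
  seed <- as.integer(config$seed %||% 1L)

  # ---- fail-fast validation before any stage runs --------------------------
  if (!is.null(config$membrane) && !is.null(config$input))
    stop("config: give either 'membrane' (synthetic) or 'input', not both")
  if (is.null(config$membrane) && is.null(config$input) &&
      is.null(config$wham))
    stop("config: nothing to do (no membrane, input or wham block)")
  for (p in c(config$input$trajectory, config$input$composition,
              config$membrane$composition, config$wham$windows))
    if (!is.null(p) && !file.exists(p)) stop("config references missing file: ", p)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  params <- list(seed = seed)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files <<- c(files, name)
    path
  }
  write_matrix_csv <- function(m, path) {
    g <- attr(m, "grid")
    hdr <- sprintf("# nx=%d ny=%d spacing=%g box_x=%g box_y=%g",
                   g$nx, g$ny, g$spacing, g$box_x, g$box_y)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(unclass(m), con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }

  traj <- NULL; comp <- NULL; truth <- NULL
  stage <- "setup"
  run_stage <- function(name, code) {
    stage <<- name
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs: ", paste(files, collapse = ", "), ")",
           call. = FALSE))
  }

  if (!is.null(config$membrane)) {
    run_stage("generate", {
      mcfg <- config$membrane
      comp_path <- mcfg$composition %||%
        system.file("extdata", "plasma_membrane_composition.csv",
                    package = "memshadow")
      comp <- read_composition(comp_path)
      n_frames <- mcfg$n_frames %||% 1L
      args <- mcfg[setdiff(names(mcfg), c("composition", "n_frames"))]
      args$composition <- comp
      args$seed <- args$seed %||% seed
      spec <- do.call(membrane_spec, args)
      params$membrane <- args[setdiff(names(args), "composition")]
      gen <- build_membrane(spec, n_frames = n_frames)
      traj <- gen$trajectory
      truth <- gen$truth
      emit("membrane.gro", function(p) write_frames(traj, p))
      emit("ground_truth.json", function(p)
        jsonlite::write_json(list(
          target = truth$target, strength = truth$strength,
          np_resids = truth$np_resids,
          cluster_members = truth$cluster_members,
          leaflet_lipid = truth$leaflet_lipid,
          undulation_modes = truth$undulation_modes),
          p, auto_unbox = TRUE, digits = NA))
    })
  } else if (!is.null(config$input)) {
    run_stage("load", {
      comp <- read_composition(config$input$composition)
      traj <- read_frames(config$input$trajectory, composition = comp)
    })
  }

  an <- config$analyses %||% list()
  if (!is.null(traj)) {
    tails <- sort(unique(stats::na.omit(
      c(comp$entries$tail1, comp$entries$tail2))))
    mk_targets <- function() {
      t <- lapply(tails, function(tc) tail_selector(comp, tc))
      names(t) <- tails
      if (any(comp$entries$headgroup == "CHOL"))
        t$CHOL <- sterol_selector(comp)
      t
    }
    if (!is.null(an$colocal)) run_stage("colocal", {
      gs <- an$colocal$grid_spacing %||% 0.5
      tab <- colocalization_table(traj, np_selector(comp), mk_targets(),
                                  grid_spacing = gs)
      params$colocal <- list(grid_spacing = gs)
      emit("colocal_table.csv", function(p)
        utils::write.csv(as.data.frame(tab), p, row.names = FALSE))
    })
    if (!is.null(an$density)) run_stage("density", {
      bw <- an$density$bin_width %||% 0.1
      sels <- list(PO4 = species_selector(beads = "^PO4$", label = "PO4"),
                   NP = np_selector(comp))
      prof <- density_profile(traj, sels, bin_width = bw)
      params$density <- list(bin_width = bw)
      emit("density_profile.csv", function(p)
        utils::write.csv(as.data.frame(prof), p, row.names = FALSE))
    })
    if (!is.null(an$enrichment)) run_stage("enrichment", {
      gs <- an$enrichment$grid_spacing %||% 1
      sels <- c(list(NP = np_selector(comp)), mk_targets())
      params$enrichment <- list(grid_spacing = gs)
      for (nm in names(sels)) {
        m <- enrichment_map(traj, sels[[nm]], grid_spacing = gs)
        emit(paste0("enrichment_", nm, ".csv"),
             function(p) write_matrix_csv(m, p))
      }
    })
    if (!is.null(an$thickness)) run_stage("thickness", {
      gs <- an$thickness$grid_spacing %||% 1
      tm <- thickness_map(traj, grid_spacing = gs)
      params$thickness <- list(grid_spacing = gs)
      emit("thickness_map.csv", function(p) write_matrix_csv(tm, p))
    })
    if (!is.null(an$undulation)) run_stage("undulation", {
      um <- undulation_metric(traj)
      emit("undulation.csv", function(p) {
        df <- um$spectrum
        df$rms <- um$rms
        utils::write.csv(df, p, row.names = FALSE)
      })
    })
    if (!is.null(an$clusters)) run_stage("clusters", {
      ct <- an$clusters$cutoff %||% 1.0
      ts <- aggregation_timeseries(traj, np_selector(comp), cutoff = ct)
      params$clusters <- list(cutoff = ct)
      emit("clusters.csv", function(p)
        utils::write.csv(ts, p, row.names = FALSE))
    })
    if (!is.null(an$unsat)) run_stage("unsat", {
      uh <- unsaturation_histogram(comp)
      emit("unsaturation.csv", function(p)
        utils::write.csv(as.data.frame(uh), p, row.names = FALSE))
    })
  }

  if (!is.null(config$wham)) run_stage("wham", {
    w <- config$wham
    windows <- read_umbrella_windows(w$windows)
    bw <- w$bin_width %||% 0.05
    temp <- w$temperature %||% 298
    nb <- w$n_boot %||% 0
    prof <- if (nb >= 20)
      bootstrap_pmf(windows, n_boot = nb, seed = seed, bin_width = bw,
                    temperature = temp)
    else wham_solve(windows, bin_width = bw, temperature = temp)
    params$wham <- list(bin_width = bw, temperature = temp, n_boot = nb)
    emit("pmf.csv", function(p)
      utils::write.csv(as.data.frame(prof), p, row.names = FALSE))
  })

  manifest <- list(
    package = "memshadow",
    version = as.character(utils::packageVersion("memshadow")),
    seed = seed,
    parameters = params,
    inputs = list(trajectory = config$input$trajectory,
                  composition = config$input$composition %||%
                    config$membrane$composition,
                  wham_windows = config$wham$windows),
    outputs = lapply(files, function(f) list(
      file = f,
      md5 = unname(tools::md5sum(file.path(outdir, f))))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
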