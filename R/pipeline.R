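# Pipeline orchestration: a config-driven wrapper over the package functions
# (simulate -> calibrate -> build-db -> segment -> export-mc [-> gamma]) with
# a machine-readable JSON report. The exported functions are the interface;
# inst/cli/rhozeff.R wraps them for shell use.

#' Build a validated pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param grid_start,grid_stop,grid_step Tissue-database grid (g/cm3).
#' @param air_threshold Segmentation air threshold (HU).
#' @param dd,dta,gamma_threshold Gamma criteria: dose difference (%),
#'   distance-to-agreement (mm), evaluation isodose (%).
#' @param sigma Simulated HU noise standard deviation.
#' @param seed Integer seed for all stochastic stages.
#' @param phantom Which default phantom to simulate (`"mouse"` or
#'   `"cylinders"`).
#' @param points_csv Optional CSV of measured calibration points
#'   (`rho_zeff`, `hu`); when `NULL` the simulated insert scan is used.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir = "rhozeff-out",
                       grid_start = 2.0, grid_stop = 26.8, grid_step = 0.2,
                       air_threshold = -850,
                       dd = 4, dta = 0.3, gamma_threshold = 10,
                       sigma = 10, seed = 1L,
                       phantom = c("mouse", "cylinders"),
                       points_csv = NULL) {
  phantom <- match.arg(phantom)
  if (dd <= 0 || dta <= 0 || gamma_threshold <= 0) {
    abort("Gamma criteria (dd, dta, threshold) must all be positive.")
  }
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (!is.null(points_csv) && !file.exists(points_csv)) {
    abort(paste0("Calibration points file not found: ", points_csv))
  }
  tissue_grid(grid_start, grid_stop, grid_step)  # validates the grid
  structure(
    list(out_dir = out_dir, grid_start = grid_start, grid_stop = grid_stop,
         grid_step = grid_step, air_threshold = air_threshold,
         dd = dd, dta = dta, gamma_threshold = gamma_threshold,
         sigma = sigma, seed = as.integer(seed), phantom = phantom,
         points_csv = points_csv),
    class = "run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config: ", path))
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes, in order: phantom simulation (ground truth + noisy CBCT volume),
#' calibration-curve fit, tissue-database construction, voxel segmentation,
#' and Monte Carlo material export; every artifact lands in `config$out_dir`
#' and a JSON report records the package version, the configuration, the seed
#' and the MD5 hash of every written file. Inputs are never mutated and
#' rerunning an identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  curve <- stage("calibrate", {
    pts <- if (is.null(config$points_csv)) {
      simulated_insert_points()
    } else {
      tibble::as_tibble(read.csv(config$points_csv))
    }
    c <- fit_hu_curve(pts)
    write_hu_curve(c, out("curve.json"))
    artifacts <- c(artifacts, out("curve.json"))
    c
  })

  db <- stage("build-db", {
    d <- build_tissue_db(curve, tissue_grid(config$grid_start, config$grid_stop,
                                            config$grid_step))
    write_tissue_db(d, out("tissues.json"))
    write_tissue_db_csv(d, out("tissues.csv"))
    artifacts <- c(artifacts, out("tissues.json"), out("tissues.csv"))
    d
  })

  sim <- stage("simulate", {
    spec <- make_default_phantoms()[[config$phantom]]
    truth <- rasterize_phantom(spec)
    vol <- simulate_hu(truth, icru_rho_zeff(), curve,
                       sigma = config$sigma, seed = config$seed)
    write_volume(vol, out("cbct.mhd"), element_type = "MET_FLOAT")
    write_volume(truth, out("truth.mhd"))
    artifacts <- c(artifacts, out("cbct.mhd"), out("truth.mhd"))
    list(truth = truth, volume = vol)
  })

  labels <- stage("segment", {
    l <- segment_volume(sim$volume, db, air_threshold = config$air_threshold)
    write_volume(l, out("labels.mhd"))
    write_legend(l, out("legend.json"))
    artifacts <- c(artifacts, out("labels.mhd"), out("legend.json"))
    l
  })

  stage("export-mc", {
    export_mc_materials(db, out("materials.db"), out("hu_ranges.txt"))
    artifacts <- c(artifacts, out("materials.db"), out("hu_ranges.txt"))
  })

  report <- list(
    tool = "rhozeff",
    version = as.character(utils::packageVersion("rhozeff")),
    config = unclass(config),
    seed = config$seed,
    n_tissues = nrow(db$tissues),
    curve_r_squared = curve$r_squared,
    n_voxels = length(labels$labels),
    label_histogram = label_histogram(labels),
    artifacts = tibble::tibble(
      path = artifacts,
      md5 = unname(tools::md5sum(artifacts))
    )
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(report)
}

#' Read/write a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return The writer returns `path` invisibly; the reader a
#'   [phantom_spec()].
#' @export
write_phantom_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(list(dim = spec$dim, spacing = spec$spacing,
                        origin = spec$origin, background = spec$background,
                        regions = lapply(seq_len(nrow(spec$regions)), function(i) {
                          as.list(spec$regions[i, ])
                        })), path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(dim = unlist(y$dim), spacing = unlist(y$spacing),
               origin = unlist(y$origin),
               regions = bind_rows(lapply(y$regions, tibble::as_tibble)),
               background = y$background)
}
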