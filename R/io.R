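# Sweep-dataset container: a directory of plain-text artifacts
#   meta.json                  resolved config, seed, schema version
#   positions.csv              i, x_mm, y_mm, z_mm
#   time_ps.csv                bin centres
#   <channel>_expected.csv     n_bins x n_pos noiseless curves
#   <channel>_baseline_expected.csv
#   <channel>_dtofs.csv        long-by-replicate count matrices (if noisy)
#   <channel>_baseline_dtofs.csv

SWEEP_SCHEMA <- "dtofsens-sweep-1"

write_matrix_csv <- function(m, path) {
  # %.17g guarantees binary round-trip of doubles through the text container
  df <- tibble::as_tibble(as.data.frame(matrix(sprintf("%.17g", m), nrow(m))),
                          .name_repair = "minimal")
  names(df) <- paste0("c", seq_len(ncol(df)))
  readr::write_csv(df, path, progress = FALSE, quote = "none")
}

read_matrix_csv <- function(path) {
  # parse via strtod (correctly rounded) rather than the approximate fast
  # float path, so containers round-trip bit-exactly
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  vapply(df, as.numeric, numeric(nrow(df)))
}

#' Write / read a sweep dataset container
#'
#' Serializes a [simulate_sweep()] dataset to a directory of CSV matrices
#' plus a JSON metadata file, and reads it back bit-exactly. Poisson
#' replicate stacks are stored per channel as `n_bins x (n_pos * n_rep)`
#' matrices with replicates blocked column-wise.
#'
#' @param dataset A `sweep_dataset`.
#' @param path Directory to create/read.
#' @return `write_sweep_dataset()` returns `path` invisibly;
#'   `read_sweep_dataset()` returns the reconstructed `sweep_dataset`.
#' @export
write_sweep_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sweep_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset$meta
  meta$tgrid <- dataset$tgrid[c("t_max", "n_bins")]
  meta$grid_axes <- dataset$grid[c("x_mm", "y_mm", "z_mm",
                                   "x_step_mm", "y_step_mm", "z_step_mm")]
  meta$channels <- dataset$channels
  meta$has_replicates <- !is.null(dataset$dtofs)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(dataset$positions, file.path(path, "positions.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::tibble(time_ps = dataset$tgrid$time_ps),
                   file.path(path, "time_ps.csv"), progress = FALSE)
  for (nm in dataset$channels$name) {
    write_matrix_csv(dataset$expected[[nm]],
                     file.path(path, paste0(nm, "_expected.csv")))
    write_matrix_csv(cbind(dataset$baseline_expected[[nm]]),
                     file.path(path, paste0(nm, "_baseline_expected.csv")))
    if (!is.null(dataset$dtofs)) {
      d <- dataset$dtofs[[nm]]
      write_matrix_csv(matrix(d, nrow = dim(d)[1]),
                       file.path(path, paste0(nm, "_dtofs.csv")))
      write_matrix_csv(dataset$baseline_dtofs[[nm]],
                       file.path(path, paste0(nm, "_baseline_dtofs.csv")))
    }
  }
  invisible(path)
}

#' @rdname write_sweep_dataset
#' @export
read_sweep_dataset <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a sweep dataset: missing ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SWEEP_SCHEMA)) {
    stop("unsupported container schema: ", meta$schema_version, call. = FALSE)
  }
  tg <- time_grid(meta$tgrid$t_max, meta$tgrid$n_bins)
  positions <- readr::read_csv(file.path(path, "positions.csv"),
                               show_col_types = FALSE, progress = FALSE)
  channels <- tibble::as_tibble(meta$channels)
  grid <- structure(
    c(list(positions = positions), meta$grid_axes),
    class = "sweep_grid"
  )
  expected <- list(); baseline_expected <- list()
  dtofs <- NULL; baseline_dtofs <- NULL
  if (isTRUE(meta$has_replicates)) { dtofs <- list(); baseline_dtofs <- list() }
  n_pos <- nrow(positions)
  for (nm in channels$name) {
    expected[[nm]] <- unname(read_matrix_csv(
      file.path(path, paste0(nm, "_expected.csv"))
    ))
    baseline_expected[[nm]] <- drop(unname(read_matrix_csv(
      file.path(path, paste0(nm, "_baseline_expected.csv"))
    )))
    if (isTRUE(meta$has_replicates)) {
      flat <- unname(read_matrix_csv(file.path(path, paste0(nm, "_dtofs.csv"))))
      nr <- ncol(flat) / n_pos
      dtofs[[nm]] <- array(flat, dim = c(nrow(flat), n_pos, nr))
      baseline_dtofs[[nm]] <- unname(read_matrix_csv(
        file.path(path, paste0(nm, "_baseline_dtofs.csv"))
      ))
    }
  }
  keep <- setdiff(names(meta), c("tgrid", "grid_axes", "channels", "has_replicates"))
  structure(
    list(
      expected = expected, baseline_expected = baseline_expected,
      dtofs = dtofs, baseline_dtofs = baseline_dtofs,
      positions = positions, channels = channels, grid = grid, tgrid = tg,
      meta = meta[keep]
    ),
    class = "sweep_dataset"
  )
}

# ---- run configuration ------------------------------------------------------

config_schema <- function() {
  list(
    optics = c("mu_a", "mu_s_prime", "n", "boundary"),
    geometry = c("far_separation_mm", "near_separation_mm"),
    grid = c("x_extent_mm", "x_step_mm", "y_extent_mm", "y_step_mm",
             "z_extent_mm", "z_step_mm", "z_offset_mm"),
    inclusion = c("diameter_mm", "height_mm", "dmu_a"),
    noise = c("counts_per_dtof", "n_replicates", "irf_fwhm_ps", "poisson",
              "deadtime_tau_ps", "collection_time_s"),
    time = c("t_max_ps", "n_bins"),
    analysis = c("log_base", "truncation_fraction", "truncation_mode",
                 "selectivity_thickness_layers", "top_thickness_mm",
                 "drop_first", "n_average", "deadtime_correct"),
    seed = NULL
  )
}

config_defaults <- function() {
  list(
    optics = list(mu_a = 0.1, mu_s_prime = 10, n = 1.33, boundary = "extrapolated"),
    geometry = list(far_separation_mm = 30, near_separation_mm = 25),
    grid = list(x_extent_mm = 75, x_step_mm = 2, y_extent_mm = 20, y_step_mm = 1,
                z_extent_mm = 35, z_step_mm = 2, z_offset_mm = 2.5),
    inclusion = list(diameter_mm = 3, height_mm = 5, dmu_a = 0.25),
    noise = list(counts_per_dtof = 157500, n_replicates = 20, irf_fwhm_ps = 650,
                 poisson = TRUE, deadtime_tau_ps = 0, collection_time_s = 0.09),
    time = list(t_max_ps = 10000, n_bins = 4096),
    analysis = list(log_base = "natural", truncation_fraction = 0.01,
                    truncation_mode = "baseline",
                    selectivity_thickness_layers = 3, top_thickness_mm = 15,
                    drop_first = 10, n_average = 10, deadtime_correct = TRUE),
    seed = 1
  )
}

#' Load and validate a run configuration
#'
#' Configurations are YAML (or an equivalent nested list) with sections
#' `optics`, `geometry`, `grid`, `inclusion`, `noise`, `time`, `analysis`
#' and a top-level `seed`. All lengths are millimetres, all times
#' picoseconds. Unknown keys are rejected; missing keys take package
#' defaults; every numeric field is validated. The fully resolved
#' configuration is embedded in every output artifact.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The resolved configuration list (class `run_config`).
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  resolved <- config_defaults()
  for (sec in names(config)) {
    if (sec == "seed") { resolved$seed <- config$seed; next }
    keys <- names(config[[sec]])
    unknown <- setdiff(keys, schema[[sec]])
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    resolved[[sec]][keys] <- config[[sec]]
  }
  validate_config(resolved)
  class(resolved) <- "run_config"
  resolved
}

validate_config <- function(cfg) {
  need_pos <- function(sec, key) {
    v <- cfg[[sec]][[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("config field %s.%s must be a positive number", sec, key),
           call. = FALSE)
    }
  }
  for (key in c("mu_a", "mu_s_prime", "n")) need_pos("optics", key)
  for (key in c("far_separation_mm", "near_separation_mm")) need_pos("geometry", key)
  if (cfg$geometry$far_separation_mm <= cfg$geometry$near_separation_mm) {
    stop("config: geometry.far_separation_mm must exceed near_separation_mm",
         call. = FALSE)
  }
  for (key in config_schema()$grid) need_pos("grid", key)
  for (key in c("diameter_mm", "height_mm")) need_pos("inclusion", key)
  for (key in c("counts_per_dtof", "n_replicates", "collection_time_s")) {
    need_pos("noise", key)
  }
  for (key in c("t_max_ps", "n_bins")) need_pos("time", key)
  if (!cfg$analysis$log_base %in% c("natural", "log10")) {
    stop("config: analysis.log_base must be 'natural' or 'log10'", call. = FALSE)
  }
  tf <- cfg$analysis$truncation_fraction
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) {
    stop("config: analysis.truncation_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("config: seed must be a single integer", call. = FALSE)
  }
  invisible(cfg)
}

config_objects <- function(cfg) {
  list(
    props = optical_properties(cfg$optics$mu_a, cfg$optics$mu_s_prime,
                               n = cfg$optics$n, boundary = cfg$optics$boundary),
    geometry = optode_geometry(cfg$geometry$far_separation_mm / 10,
                               cfg$geometry$near_separation_mm / 10),
    grid = do.call(sweep_grid, cfg$grid),
    incl = inclusion(cfg$inclusion$diameter_mm, cfg$inclusion$height_mm,
                     cfg$inclusion$dmu_a),
    noise = do.call(noise_config, cfg$noise),
    tgrid = time_grid(cfg$time$t_max_ps, cfg$time$n_bins)
  )
}

#' Simulate a sweep from a configuration and write it to disk
#'
#' @param config Path to a YAML configuration or a nested list
#'   (see [load_config()]).
#' @param out_dir Output directory for the sweep container.
#' @param seed Optional seed overriding the configuration's.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ob <- config_objects(cfg)
  ds <- simulate_sweep(ob$props, ob$geometry, ob$grid, ob$incl, ob$noise,
                       ob$tgrid, seed = cfg$seed)
  ds$meta$config <- unclass(cfg)
  write_sweep_dataset(ds, out_dir)
  message(sprintf("wrote sweep dataset (%d positions, seed %d) to %s",
                  nrow(ds$positions), cfg$seed, out_dir))
  invisible(out_dir)
}

#' Analyze a sweep container and write maps, metrics and a report
#'
#' Runs [assemble_maps()], [depth_profile()], [depth_selectivity()],
#' [photon_noise_sd()] and [overall_performance()] on a stored (or
#' in-memory) sweep dataset and writes: per-plane map projections and the
#' full voxel maps (CSV), depth profiles, selectivity curves and the
#' performance table (CSV), a JSON metrics bundle, and a short
#' human-readable report.
#'
#' @param dataset A sweep container directory or a `sweep_dataset`.
#' @param out_dir Output directory.
#' @param config Optional YAML path or list overriding analysis settings.
#' @return Invisibly, a list with `maps`, `profile`, `selectivity`, `noise`
#'   and `performance`.
#' @export
run_analyze <- function(dataset, out_dir, config = list()) {
  cfg <- load_config(config)
  if (is.character(dataset)) dataset <- read_sweep_dataset(dataset)
  stopifnot(inherits(dataset, "sweep_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- cfg$analysis
  maps <- assemble_maps(
    dataset,
    drop_first = an$drop_first, n_average = an$n_average,
    threshold_fraction = an$truncation_fraction,
    truncation_mode = an$truncation_mode, log_base = an$log_base,
    deadtime_correct = an$deadtime_correct
  )
  profile <- depth_profile(maps)
  selectivity <- depth_selectivity(
    maps, thickness_layers = an$selectivity_thickness_layers
  )
  noise <- photon_noise_sd(attr(maps, "baseline_moments"))
  performance <- overall_performance(maps, noise,
                                     top_thickness_mm = an$top_thickness_mm)

  readr::write_csv(tibble::as_tibble(maps), file.path(out_dir, "maps.csv"),
                   progress = FALSE)
  for (plane in c("xz", "yz", "xy")) {
    readr::write_csv(project_maps(maps, plane),
                     file.path(out_dir, paste0("maps_", plane, ".csv")),
                     progress = FALSE)
  }
  readr::write_csv(tibble::as_tibble(profile),
                   file.path(out_dir, "depth_profile.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(selectivity),
                   file.path(out_dir, "depth_selectivity.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(performance),
                   file.path(out_dir, "performance.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      noise_model = noise, performance = performance,
      peak_depths = peak_sensitivity_depth(profile),
      config = unclass(cfg)
    ),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  writeLines(analysis_report(maps, performance), file.path(out_dir, "report.txt"))
  invisible(list(maps = maps, profile = profile, selectivity = selectivity,
                 noise = noise, performance = performance))
}

analysis_report <- function(maps, performance) {
  mx <- max(abs(maps$value[maps$moment == "A"]))
  hdr <- c(
    "dtofsens analysis report",
    sprintf("positions: %d; methods: %s", length(unique(maps$i)),
            paste(unique(maps$method), collapse = ", ")),
    if (mx == 0) "no perturbation detected: all attenuation maps are zero"
    else sprintf("peak |dA| on any channel: %.4g", mx),
    "",
    "overall performance (S x CNR), top layer split:"
  )
  perf <- tibble::as_tibble(performance)
  rows <- sprintf(
    "  %-14s %-3s S = %9.4g  CNR = %9.4g  S*CNR = %9.4g",
    perf$method, perf$moment, perf$S, perf$CNR, perf$performance
  )
  c(hdr, rows)
}
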