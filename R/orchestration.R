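#' Pipeline configuration
#'
#' Builds the configuration for the three pipeline experiments: the inflow
#' production grid, the coverage/production atmospheric surface, and the
#' instrument detection-time table. Every default equals the standard study
#' value; any key supplied must already exist in the defaults (unknown keys
#' are rejected, catching typos instead of silently ignoring them).
#'
#' @param ... Named overrides of the default configuration, as nested lists,
#'   e.g. `grid = list(n_inflow = 5)`, `detectability = list(distances_pc = 10)`.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    reactor = list(
      temperature = 300, pressure = 250e5, volume = 1,
      conc_co2 = 1e-3, conc_h2 = 1e-2, conc_ch4 = 2e-3,
      dt = 1000, t_end = 1e8, averaging_window = 1e7,
      maintenance_power = 5.32e-14, max_metabolic_rate = 1.06e-18,
      rate_constant = 2.88e-5, life_span = 1e6,
      synthesis_energy = 1e-11, founder_population = 500),
    grid = list(n_inflow = 21, inflow_min = 1e-12, inflow_max = 1e-6),
    atmosphere = list(
      eta = c(1.0, 0.2), ocean_area_preset = "headline", vent_height = 10,
      abiotic_flux = 10, thresholds = c(0.0005, 0.0025, 0.01),
      coverage_min = 1e-10, coverage_max = 1, n_coverage = 41,
      rate_min = 1e-17, rate_max = 1e-6, n_rate = 45),
    detectability = list(
      instruments = c("LUVOIR A", "LUVOIR B", "HabEx SS", "HabEx no SS"),
      distances_pc = c(5, 10, 15, 20),
      ch4_fractions = c(0.0025, 0.01),
      baseline_ch4 = 0.0005, exposure_time_h = 100,
      include_6m = FALSE, iwa_policy = "flag"),
    output_dir = ".",
    log_level = "info")
  cfg <- merge_config(defaults, list(...), path = "")
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("configuration overrides must be named (at '", path, "')")
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in nm) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(overrides[[k]]),
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the same nested structure as [pipeline_config()]; keys not
#' present keep their defaults and unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, as.list(raw))
}

## short deterministic hash of the configuration, for CSV headers
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(substr(tools::md5sum(tf), 1, 12))
}

log_msg <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(sprintf(...))
}

## deterministic CSV writer: scientific notation at 9 significant digits,
## header comment carrying the config hash (never a timestamp)
write_pipeline_csv <- function(df, path, hash) {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.9e", col) else as.character(col)
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(c(sprintf("# config_hash: %s", hash),
               paste(names(df), collapse = ","), body), path)
  invisible(path)
}

reactor_inputs_from_config <- function(config) {
  r <- config$reactor
  list(config = reactor_config(temperature = r$temperature, pressure = r$pressure,
                               volume = r$volume, conc_co2 = r$conc_co2,
                               conc_h2 = r$conc_h2, conc_ch4 = r$conc_ch4,
                               dt = r$dt, t_end = r$t_end,
                               averaging_window = r$averaging_window),
       traits = organism_traits(maintenance_power = r$maintenance_power,
                                max_metabolic_rate = r$max_metabolic_rate,
                                rate_constant = r$rate_constant,
                                life_span = r$life_span,
                                synthesis_energy = r$synthesis_energy,
                                founder_population = r$founder_population))
}

#' Run the inflow production-grid experiment
#'
#' Sweeps the factorial CO2 x H2 inflow grid (21 x 21 log-spaced points over
#' 1e-12 to 1e-6 mol/L/s by default, 441 simulations), writes the grid as
#' CSV and a JSON summary reporting the grid extremes and the inflow pairs
#' at which they occur.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `production_grid` object and the paths
#'   written (`csv`, `json`).
#' @export
run_production_grid_experiment <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(config$output_dir, "production_grid.csv")
  json_path <- file.path(config$output_dir, "production_grid_summary.json")
  if (file.access(config$output_dir, 2) != 0) {
    stop("output directory is not writable: ", config$output_dir)
  }
  axis <- default_inflow_axis(config$grid$n_inflow, config$grid$inflow_min,
                              config$grid$inflow_max)
  inp <- reactor_inputs_from_config(config)
  log_msg(config, "running %d reactor simulations", length(axis)^2)
  grid <- run_grid(axis, axis, inp$config, inp$traits,
                   verbose = !identical(config$log_level, "quiet"))
  hash <- config_hash(config)
  write_pipeline_csv(as.data.frame(grid), csv_path, hash)

  mp <- grid$mean_production
  i_min <- which(mp == min(mp, na.rm = TRUE), arr.ind = TRUE)[1, ]
  i_max <- which(mp == max(mp, na.rm = TRUE), arr.ind = TRUE)[1, ]
  summary <- list(
    n_simulations = length(mp),
    min_production_mol_per_l_s = min(mp, na.rm = TRUE),
    min_at = list(inflow_co2 = axis[i_min[1]], inflow_h2 = axis[i_min[2]]),
    max_production_mol_per_l_s = max(mp, na.rm = TRUE),
    max_at = list(inflow_co2 = axis[i_max[1]], inflow_h2 = axis[i_max[2]]),
    n_failed = sum(!is.finite(mp)),
    config_hash = hash)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  log_msg(config, "grid written to %s", csv_path)
  invisible(list(grid = grid, csv = csv_path, json = json_path))
}

#' Run the coverage/production atmospheric surface experiment
#'
#' Evaluates the atmospheric methane mixing ratio over a log grid of vent
#' production rates and ocean-floor coverage fractions, once per outgassing
#' preset (best case eta = 1 and conservative eta = 0.2 by default), writes
#' one surface CSV per eta and one threshold-contour CSV (coverage required
#' at each rate) per biogenicity threshold.
#'
#' @param config A [pipeline_config()].
#' @param rates Optional explicit production-rate axis, mol/L/s; by default
#'   a log axis from the configuration.
#' @return Invisibly, a list with the surface data frame and paths written.
#' @export
run_atmosphere_surface <- function(config = pipeline_config(), rates = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  a <- config$atmosphere
  if (is.null(rates)) {
    rates <- 10^seq(log10(a$rate_min), log10(a$rate_max), length.out = a$n_rate)
  }
  coverages <- 10^seq(log10(a$coverage_min), log10(a$coverage_max),
                      length.out = a$n_coverage)
  hash <- config_hash(config)
  paths <- character(0)
  surfaces <- list()
  for (eta in a$eta) {
    model <- vent_coverage_model(vent_height = a$vent_height,
                                 outgassing_fraction = eta,
                                 abiotic_flux = a$abiotic_flux,
                                 ocean_area_preset = a$ocean_area_preset)
    g <- expand.grid(production_rate_mol_per_l_s = rates,
                     coverage_fraction = coverages, KEEP.OUT.ATTRS = FALSE)
    vol <- vent_volume(g$coverage_fraction, model$ocean_area, model$vent_height)
    fl <- global_flux(g$production_rate_mol_per_l_s, vol, eta, a$abiotic_flux)
    g$eta <- eta
    g$total_flux_tmol_per_yr <- fl$total_flux
    g$mixing_ratio <- fl$mixing_ratio
    g$classification <- classify_mixing_ratio(fl$mixing_ratio)
    p <- file.path(config$output_dir,
                   sprintf("atmosphere_surface_eta_%s.csv", format(eta)))
    write_pipeline_csv(g, p, hash)
    paths <- c(paths, p)
    surfaces[[format(eta)]] <- g

    for (thr in a$thresholds) {
      cov <- suppressWarnings(coverage_for_mixing(rates, thr, model))
      contour <- data.frame(production_rate_mol_per_l_s = rates,
                            coverage_fraction = as.numeric(cov),
                            flag = attr(cov, "flag"))
      pc <- file.path(config$output_dir,
                      sprintf("contour_f%g_eta_%s.csv", thr, format(eta)))
      write_pipeline_csv(contour, pc, hash)
      paths <- c(paths, pc)
    }
  }
  log_msg(config, "atmosphere surfaces written to %s", config$output_dir)
  invisible(list(surfaces = surfaces, paths = paths))
}

#' Run the instrument detection-time experiment
#'
#' Crosses the configured instruments (optionally with their 6 m rescaled
#' variants), observer distances and candidate methane fractions, computing
#' the 100 h integrated S/N and 5-sigma detection time of each combination
#' against the configured baseline. Infeasible IWA combinations are flagged,
#' not dropped.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the detection table and the CSV path.
#' @export
run_detection_table <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  d <- config$detectability
  known <- standard_instruments()
  unknown <- setdiff(d$instruments, names(known))
  if (length(unknown)) {
    stop("unknown instrument name(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(names(known), collapse = ", "))
  }
  instruments <- known[d$instruments]
  if (isTRUE(d$include_6m)) {
    six <- lapply(known[c("HabEx SS", "LUVOIR B")], rescale_mirror, 6)
    names(six) <- vapply(six, `[[`, "", "name")
    instruments <- c(instruments, six)
  }
  bands <- default_band_library()
  rows <- list()
  for (nm in names(instruments)) {
    for (dist in d$distances_pc) {
      sc <- scene(distance_pc = dist, exposure_time_h = d$exposure_time_h)
      for (f in d$ch4_fractions) {
        res <- detect_methane(f, instruments[[nm]], sc,
                              baseline_ch4 = d$baseline_ch4, bands = bands,
                              iwa_policy = d$iwa_policy)
        rows[[length(rows) + 1L]] <- data.frame(
          instrument = nm,
          aperture_m = instruments[[nm]]$aperture_diameter,
          distance_pc = dist, ch4_fraction = f,
          snr_100h = res$snr, t5sigma_h = res$t_5sigma,
          feasible = res$feasible)
      }
    }
  }
  tab <- do.call(rbind, rows)
  path <- file.path(config$output_dir, "detection_times.csv")
  write_pipeline_csv(tab, path, config_hash(config))
  log_msg(config, "detection table written to %s", path)
  invisible(list(table = tab, csv = path))
}

#' Run the full pipeline
#'
#' The production grid, the atmospheric surface (fed by the grid's
#' production-rate range) and the detection table, in order.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the three experiment results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  grid <- run_production_grid_experiment(config)
  mp <- grid$grid$mean_production
  rates <- range(mp[is.finite(mp) & mp > 0])
  surface <- run_atmosphere_surface(
    config, rates = 10^seq(log10(rates[1]), log10(rates[2]), length.out = 25))
  detection <- run_detection_table(config)
  invisible(list(grid = grid, surface = surface, detection = detection))
}
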