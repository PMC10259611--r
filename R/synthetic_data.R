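#' Gaussian molecular band library
#'
#' Constructs a band library: for each gas, a set of Gaussian absorption
#' bands in wavelength with a centre (um), a 1-sigma width (um) and a peak
#' cross section (m2/molecule), valid over a stated wavelength range. This
#' stands in for a line-by-line spectroscopic database in the toy
#' reflected-light model; band-averaged behaviour, not line fidelity, is the
#' goal.
#'
#' @param bands Named list (by gas) of data frames with columns `center_um`,
#'   `width_um`, `peak_m2`.
#' @param validity_um Length-2 numeric, wavelength validity range in um.
#' @return An object of class `band_library`.
#' @export
band_library <- function(bands, validity_um) {
  stopifnot(is.list(bands), length(validity_um) == 2L, diff(validity_um) > 0)
  for (g in names(bands)) {
    b <- bands[[g]]
    stopifnot(all(c("center_um", "width_um", "peak_m2") %in% names(b)))
    if (any(b$width_um <= 0) || any(b$peak_m2 <= 0) || any(!is.finite(b$peak_m2))) {
      stop("band widths and peak cross sections must be positive and finite (gas ", g, ")")
    }
    if (any(b$center_um < validity_um[1] | b$center_um > validity_um[2])) {
      stop("band centre outside validity range (gas ", g, ")")
    }
  }
  structure(list(bands = bands, validity_um = validity_um), class = "band_library")
}

#' Default near-infrared band library
#'
#' Deterministic library of Gaussian stand-in bands for CH4, CO2 and H2O at
#' standard visible/near-infrared band positions (methane's 0.62-1.67 um
#' octave/combination bands, the CO2 1.2-2.0 um combination bands, the water
#' 0.94/1.12/1.40/1.87 um bands). Peak cross sections are of the order of
#' band-averaged low-resolution values, with methane's increasing towards
#' the near infrared; the CO (10 ppm) trace carries no modelled bands.
#' Absolute depths are therefore representative, not database-accurate, and
#' the pipeline asserts only orderings and scalings built on them.
#'
#' @return A `band_library` valid over 0.45-2.05 um with at least four CH4
#'   bands between 0.8 and 1.8 um.
#' @export
default_band_library <- function() {
  band_library(
    bands = list(
      CH4 = data.frame(
        center_um = c(0.619, 0.727, 0.790, 0.889, 1.000, 1.160, 1.330, 1.670),
        width_um  = c(0.005, 0.008, 0.008, 0.010, 0.012, 0.015, 0.018, 0.025),
        peak_m2   = c(4e-30, 1.5e-29, 7e-30, 6e-29, 4e-29, 1.5e-28, 4e-28, 8e-28)),
      CO2 = data.frame(
        center_um = c(1.210, 1.440, 1.600, 2.010),
        width_um  = c(0.012, 0.015, 0.015, 0.020),
        peak_m2   = c(1e-29, 2e-29, 8e-30, 3e-28)),
      H2O = data.frame(
        center_um = c(0.940, 1.120, 1.400, 1.870),
        width_um  = c(0.015, 0.015, 0.020, 0.025),
        peak_m2   = c(5e-29, 8e-29, 3e-28, 6e-28))
    ),
    validity_um = c(0.45, 2.05))
}

#' @export
print.band_library <- function(x, ...) {
  cat(sprintf("Band library valid %.2f-%.2f um\n",
              x$validity_um[1], x$validity_um[2]))
  for (g in names(x$bands)) {
    cat(sprintf("  %s: %d bands at %s um\n", g, nrow(x$bands[[g]]),
                paste(format(x$bands[[g]]$center_um), collapse = ", ")))
  }
  invisible(x)
}

#' Total absorption cross section of a gas at given wavelengths
#'
#' Sum of the gas's Gaussian bands evaluated at `lambda_um`.
#'
#' @param library A [band_library()].
#' @param gas Gas name; a gas absent from the library absorbs nothing.
#' @param lambda_um Wavelengths, um; must lie inside the validity range.
#' @return Cross sections in m2/molecule.
#' @export
cross_section <- function(library, gas, lambda_um) {
  rng <- library$validity_um
  if (any(lambda_um < rng[1] | lambda_um > rng[2])) {
    stop(sprintf("wavelength outside band-library validity range %.2f-%.2f um",
                 rng[1], rng[2]))
  }
  b <- library$bands[[gas]]
  if (is.null(b)) return(numeric(length(lambda_um)))
  sig <- numeric(length(lambda_um))
  for (i in seq_len(nrow(b))) {
    sig <- sig + b$peak_m2[i] *
      exp(-0.5 * ((lambda_um - b$center_um[i]) / b$width_um[i])^2)
  }
  sig
}

#' Serialize a band library to the plain-text key-value format
#'
#' Uses keys `<gas>.band<k>.center_um` / `.width_um` / `.peak_m2` plus
#' `validity.min_um` / `validity.max_um`, readable with
#' [read_band_library()].
#'
#' @param library A [band_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_library <- function(library, path) {
  kv <- c(validity.min_um = library$validity_um[1],
          validity.max_um = library$validity_um[2])
  for (g in names(library$bands)) {
    b <- library$bands[[g]]
    for (i in seq_len(nrow(b))) {
      kv[sprintf("%s.band%d.center_um", g, i)] <- b$center_um[i]
      kv[sprintf("%s.band%d.width_um", g, i)] <- b$width_um[i]
      kv[sprintf("%s.band%d.peak_m2", g, i)] <- b$peak_m2[i]
    }
  }
  write_key_value(kv, path, header = "Gaussian molecular band library")
}

#' @rdname write_band_library
#' @export
read_band_library <- function(path) {
  kv <- read_key_value(path)
  validity <- unname(c(kv["validity.min_um"], kv["validity.max_um"]))
  keys <- grep("\\.band[0-9]+\\.center_um$", names(kv), value = TRUE)
  gases <- unique(sub("\\.band[0-9]+\\.center_um$", "", keys))
  bands <- lapply(gases, function(g) {
    idx <- sort(as.integer(sub(sprintf("^%s\\.band([0-9]+)\\.center_um$", g), "\\1",
                               grep(sprintf("^%s\\.band[0-9]+\\.center_um$", g),
                                    names(kv), value = TRUE))))
    data.frame(center_um = kv[sprintf("%s.band%d.center_um", g, idx)],
               width_um = kv[sprintf("%s.band%d.width_um", g, idx)],
               peak_m2 = kv[sprintf("%s.band%d.peak_m2", g, idx)],
               row.names = NULL)
  })
  names(bands) <- gases
  band_library(bands, validity)
}

#' Poisson-resampled mock observation
#'
#' Perturbs the signal counts of a counts spectrum by Poisson sampling with
#' an explicit seed, for validating the S/N statistic against sampling
#' noise. The stored 1-sigma noise counts are left untouched.
#'
#' @param true_counts A `counts_spectrum` (see [observe()]).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `counts_spectrum` with Poisson-sampled signal counts.
#' @export
mock_observation <- function(true_counts, seed) {
  stopifnot(inherits(true_counts, "counts_spectrum"))
  if (missing(seed) || !is.finite(seed)) stop("an explicit integer seed is required")
  if (any(true_counts$signal < 0)) stop("expected counts must be non-negative")
  obs <- true_counts
  obs$signal <- withr_seed(seed, stats::rpois(length(true_counts$signal),
                                              true_counts$signal))
  obs
}

## evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Sawtooth production series with an exact known mean
#'
#' Deterministic stand-in for a limit-cycle production trajectory: a rising
#' sawtooth sampled on the step grid, scaled so that the discrete mean over
#' each full period equals `mean` exactly. Used to validate
#' [mean_production()] recovery to floating-point accuracy.
#'
#' @param mean Target mean production, mol/L/s.
#' @param period Cycle period, s; an integer multiple of `dt`, at least 2 dt.
#' @param duration Total span, s; an integer number of periods.
#' @param dt Step, s.
#' @return An object of class `mock_series` with `time` (s, from 0),
#'   `production` (instantaneous rate over the preceding step),
#'   `cumulative` (mol/L) and `analytic_mean`.
#' @export
sawtooth_series <- function(mean, period, duration, dt) {
  if (mean < 0 || dt <= 0) stop("mean must be >= 0 and dt > 0")
  npp <- period / dt
  if (abs(npp - round(npp)) > 1e-9 || round(npp) < 2) {
    stop("period must be an integer multiple of dt, at least 2 dt")
  }
  npp <- round(npp)
  ncyc <- duration / period
  if (abs(ncyc - round(ncyc)) > 1e-9 || round(ncyc) < 1) {
    stop("duration must be a whole number of periods")
  }
  ncyc <- round(ncyc)
  ramp <- (seq_len(npp) - 1) * 2 * mean / (npp - 1)
  prod <- rep(ramp, ncyc)
  n <- npp * ncyc
  structure(list(time = c(0, seq_len(n) * dt),
                 production = c(0, prod),
                 cumulative = c(0, cumsum(prod * dt)),
                 analytic_mean = mean, period = period, dt = dt),
            class = "mock_series")
}
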