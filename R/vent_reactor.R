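#' Energetic and kinetic traits of the modelled methanogen
#'
#' Per-cell constants for the simulated hydrogenotrophic methanogen
#' population. Defaults are the anaerobic maintenance-power estimate and the
#' methanogen kinetic constants used throughout the reactor simulations.
#'
#' @param maintenance_power J/s a cell must dissipate to stay viable.
#' @param max_metabolic_rate Per-cell cap on substrate turnover, mol/L/s in
#'   the 1 L reactor.
#' @param rate_constant First-order rate constant in CO2, 1/s.
#' @param life_span Cell life span in s; must be an integer multiple of the
#'   reactor time step. Cohorts older than this are removed (founders exempt).
#' @param synthesis_energy Energy to build one new cell, J. Not constrained
#'   by observation; mean production in the inflow-limited regime is
#'   insensitive to it because total biomass adjusts to the available energy.
#' @param founder_population Number of cells present at t = 0. The founder
#'   cohort is never removed, so the population can always recover.
#' @return An object of class `organism_traits`.
#' @export
organism_traits <- function(maintenance_power = 5.32e-14,
                            max_metabolic_rate = 1.06e-18,
                            rate_constant = 2.88e-5,
                            life_span = 1e6,
                            synthesis_energy = 1e-11,
                            founder_population = 500) {
  vals <- c(maintenance_power, max_metabolic_rate, rate_constant,
            life_span, synthesis_energy, founder_population)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all organism traits must be finite and strictly positive")
  }
  structure(list(maintenance_power = maintenance_power,
                 max_metabolic_rate = max_metabolic_rate,
                 rate_constant = rate_constant,
                 life_span = life_span,
                 synthesis_energy = synthesis_energy,
                 founder_population = founder_population),
            class = "organism_traits")
}

#' Configuration of the 1 L vent bioreactor
#'
#' Physical conditions, initial substrate stocks, substrate inflows and
#' stepper settings for one reactor simulation. Defaults reproduce the
#' standard study conditions: 300 K, 250 bar (carried as metadata; no
#' pressure correction is applied to the thermodynamics), initial CO2 1 mmol/L,
#' H2 10 mmol/L, CH4 2 mmol/L, a 1000 s time step, a 1e8 s run and
#' production averaging over the final 1e7 s. Methane accumulates in the
#' reactor for the whole run; there is no outflow.
#'
#' @param temperature K.
#' @param pressure Pa (metadata only).
#' @param volume Reactor volume, L.
#' @param conc_co2,conc_h2,conc_ch4 Initial concentrations, mol/L.
#' @param inflow_co2,inflow_h2 Constant substrate inflows, mol/L/s (>= 0).
#' @param dt Time step, s.
#' @param t_end Total simulated time, s (integer number of steps; 0 allowed).
#' @param averaging_window Window at the end of the run over which mean
#'   production is computed, s.
#' @return An object of class `reactor_config`.
#' @export
reactor_config <- function(temperature = 300, pressure = 250e5, volume = 1,
                           conc_co2 = 1e-3, conc_h2 = 1e-2, conc_ch4 = 2e-3,
                           inflow_co2 = 0, inflow_h2 = 0,
                           dt = 1000, t_end = 1e8, averaging_window = 1e7) {
  if (dt <= 0) stop("dt must be positive")
  if (t_end < 0) stop("t_end must be non-negative")
  if (averaging_window <= 0) stop("averaging_window must be positive")
  if (inflow_co2 < 0 || inflow_h2 < 0) stop("inflows must be non-negative")
  if (any(c(conc_co2, conc_h2, conc_ch4) < 0)) {
    stop("initial concentrations must be non-negative")
  }
  if (temperature <= 0 || volume <= 0) stop("temperature and volume must be positive")
  if (abs(t_end / dt - round(t_end / dt)) > 1e-9) {
    stop("t_end must be an integer number of time steps")
  }
  structure(list(temperature = temperature, pressure = pressure, volume = volume,
                 conc_co2 = conc_co2, conc_h2 = conc_h2, conc_ch4 = conc_ch4,
                 inflow_co2 = inflow_co2, inflow_h2 = inflow_h2,
                 dt = dt, t_end = t_end, averaging_window = averaging_window),
            class = "reactor_config")
}

#' Instantaneous state of the reactor
#'
#' Explicit state representation used by the single-step reference updater
#' [reactor_step()]. Cohorts are stored as parallel vectors of birth step and
#' cell count; the cohort born at step 0 is the founder cohort and is exempt
#' from life-span removal.
#'
#' @param step Integer step index (time = step * dt).
#' @param conc_co2,conc_h2,conc_ch4 Concentrations, mol/L.
#' @param cohort_birth Integer vector of birth steps.
#' @param cohort_count Numeric vector of cell counts per cohort.
#' @param active Number of cells active (metabolising) after the last step;
#'   the remainder of the living population is in stasis.
#' @param growth_energy_pool Accumulated surplus energy not yet converted to
#'   cells, J.
#' @param cumulative_ch4 Methane produced since t = 0, mol/L.
#' @return An object of class `reactor_state`.
#' @export
reactor_state <- function(step = 0L, conc_co2 = 1e-3, conc_h2 = 1e-2,
                          conc_ch4 = 2e-3, cohort_birth = 0L,
                          cohort_count = 500, active = 0,
                          growth_energy_pool = 0, cumulative_ch4 = 0) {
  st <- structure(list(step = as.integer(step),
                       conc_co2 = conc_co2, conc_h2 = conc_h2, conc_ch4 = conc_ch4,
                       cohort_birth = as.integer(cohort_birth),
                       cohort_count = as.numeric(cohort_count),
                       active = active,
                       growth_energy_pool = growth_energy_pool,
                       cumulative_ch4 = cumulative_ch4),
                  class = "reactor_state")
  validate_reactor_state(st)
  st
}

validate_reactor_state <- function(state) {
  if (any(c(state$conc_co2, state$conc_h2, state$conc_ch4) < 0) ||
      anyNA(c(state$conc_co2, state$conc_h2, state$conc_ch4))) {
    stop("invalid reactor state: negative or missing concentration")
  }
  if (any(state$cohort_count < 0)) stop("invalid reactor state: negative cohort count")
  if (length(state$cohort_birth) != length(state$cohort_count)) {
    stop("invalid reactor state: cohort vectors of unequal length")
  }
  if (!any(state$cohort_birth == 0L)) {
    stop("invalid reactor state: founder cohort (birth step 0) missing")
  }
  invisible(state)
}

#' Advance the reactor by one time step
#'
#' Reference implementation of one update of the growth/stasis/death cycle,
#' in fixed order: (1) substrate inflow; (2) thermodynamic gate - the Gibbs
#' energy of methanogenesis at current concentrations, metabolism skipped if
#' dG >= 0; (3) demand: per-cell rate R = min(k \[CO2\], r_max), total
#' turnover x = min(R N dt, \[CO2\], \[H2\]/4); (4) concentration update;
#' (5) energy accounting: E = x V |dG| supports floor(E / (P_m dt)) cells,
#' the rest of the living population rests in stasis, surplus energy accrues
#' to the growth pool and is converted to floor(pool / E_syn) new cells in a
#' new cohort; (6) cohorts (founders excepted) whose age has reached the life
#' span are removed. Stasis cells consume nothing but keep ageing and are
#' reconsidered for activity every step.
#'
#' [run_reactor()] applies exactly these rules through an equivalent
#' constant-time internal stepper; this function is the transparent
#' single-step form used for testing and extension.
#'
#' @param state A [reactor_state()].
#' @param config A [reactor_config()].
#' @param traits An [organism_traits()].
#' @param thermo A [methanogenesis_thermo()] object.
#' @return The updated `reactor_state`.
#' @export
reactor_step <- function(state, config, traits,
                         thermo = methanogenesis_thermo()) {
  validate_reactor_state(state)
  dt <- config$dt
  life_steps <- traits$life_span / dt
  if (abs(life_steps - round(life_steps)) > 1e-9) {
    stop("life_span must be an integer multiple of dt")
  }
  life_steps <- round(life_steps)
  s <- state$step + 1L

  ## (1) inflow
  co2 <- state$conc_co2 + config$inflow_co2 * dt
  h2 <- state$conc_h2 + config$inflow_h2 * dt
  ch4 <- state$conc_ch4

  ## (2) thermodynamic gate
  n_alive <- sum(state$cohort_count)
  ## CH4 floored at 1e-30 mol/L inside the gate so a product-free start does
  ## not propagate an infinite energy yield (documented numerical floor)
  dG <- if (co2 > 0 && h2 > 0) {
    gibbs_energy(config$temperature,
                 reaction_quotient(co2, h2, max(ch4, 1e-30)), thermo)
  } else {
    Inf  # no substrate, treat as unfavourable
  }
  metabolising <- dG < 0

  x <- 0
  active <- 0
  pool <- state$growth_energy_pool
  births <- 0
  if (metabolising && n_alive > 0) {
    ## (3) demand with limiting-reagent cap
    r_cell <- min(traits$rate_constant * co2, traits$max_metabolic_rate)
    x <- min(r_cell * n_alive * dt, co2, h2 / 4)
    ## (5) energy accounting (concentrations updated in (4) below)
    energy <- x * config$volume * abs(dG)
    maint <- traits$maintenance_power * dt
    n_supportable <- floor(energy / maint)
    active <- min(n_alive, n_supportable)
    if (n_supportable > n_alive) {
      pool <- pool + (energy - n_alive * maint)
      births <- floor(pool / traits$synthesis_energy)
      pool <- pool - births * traits$synthesis_energy
    }
  }
  ## (4) concentration update
  co2 <- max(co2 - x, 0)
  h2 <- max(h2 - 4 * x, 0)
  ch4 <- ch4 + x

  cohort_birth <- state$cohort_birth
  cohort_count <- state$cohort_count
  if (births > 0) {
    cohort_birth <- c(cohort_birth, s)
    cohort_count <- c(cohort_count, births)
  }
  ## (6) life-span removal, founders exempt
  keep <- cohort_birth == 0L | (s - cohort_birth) < life_steps
  cohort_birth <- cohort_birth[keep]
  cohort_count <- cohort_count[keep]

  structure(list(step = s, conc_co2 = co2, conc_h2 = h2, conc_ch4 = ch4,
                 cohort_birth = cohort_birth, cohort_count = cohort_count,
                 active = active, growth_energy_pool = pool,
                 cumulative_ch4 = state$cumulative_ch4 + x),
            class = "reactor_state")
}

#' Run a reactor simulation
#'
#' Deterministic forward-Euler integration of the vent bioreactor over
#' `t_end` seconds at time step `dt`, applying the update rules of
#' [reactor_step()] at every step. Identical inputs give identical outputs;
#' there is no randomness anywhere in the reactor.
#'
#' @inheritParams reactor_step
#' @return An object of class `reactor_sim`: a list with `series` (data frame
#'   with columns `time_s`, `population_active`, `population_total`,
#'   `conc_co2`, `conc_h2`, `conc_ch4`, `inst_production`,
#'   `cumulative_ch4`, one row per step plus the initial state), and the
#'   `config`, `traits` and `thermo` used.
#' @examples
#' cfg <- reactor_config(inflow_co2 = 1e-9, inflow_h2 = 1e-9,
#'                       t_end = 1e6, averaging_window = 1e6)
#' sim <- run_reactor(cfg)
#' mean_production(sim, 1e6)
#' @export
run_reactor <- function(config, traits = organism_traits(),
                        thermo = methanogenesis_thermo()) {
  stopifnot(inherits(config, "reactor_config"), inherits(traits, "organism_traits"))
  dt <- config$dt
  n_steps <- round(config$t_end / dt)
  life_steps <- traits$life_span / dt
  if (abs(life_steps - round(life_steps)) > 1e-9) {
    stop("life_span must be an integer multiple of dt")
  }
  life_steps <- round(life_steps)

  temperature <- config$temperature
  dG0T <- standard_gibbs_at(temperature, thermo)
  RT <- .R_GAS * temperature
  in_co2 <- config$inflow_co2 * dt
  in_h2 <- config$inflow_h2 * dt
  k <- traits$rate_constant
  rmax <- traits$max_metabolic_rate
  maint <- traits$maintenance_power * dt
  esyn <- traits$synthesis_energy
  vol <- config$volume
  founders <- traits$founder_population

  co2 <- config$conc_co2
  h2 <- config$conc_h2
  ch4 <- config$conc_ch4
  pool <- 0
  cum <- 0
  pop_nf <- 0  # non-founder living cells

  ## death queue: ring of length life_steps + 1; a cohort born at step s is
  ## removed in phase (6) of step s + life_steps, before its slot is reused
  ring_len <- life_steps + 1L
  ring <- numeric(ring_len)

  nr <- n_steps + 1L
  out <- matrix(0, nrow = nr, ncol = 8L)
  colnames(out) <- c("time_s", "population_active", "population_total",
                     "conc_co2", "conc_h2", "conc_ch4", "inst_production",
                     "cumulative_ch4")
  out[1L, ] <- c(0, 0, founders, co2, h2, ch4, 0, 0)

  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      co2 <- co2 + in_co2
      h2 <- h2 + in_h2
      n_alive <- founders + pop_nf
      x <- 0
      active <- 0
      if (co2 > 0 && h2 > 0) {
        dG <- dG0T + RT * log(max(ch4, 1e-30) / (co2 * h2 * h2 * h2 * h2))
        if (dG < 0) {
          r_cell <- min(k * co2, rmax)
          x <- r_cell * n_alive * dt
          if (x > co2) x <- co2
          if (x > h2 / 4) x <- h2 / 4
          if (x > 0) {
            energy <- x * vol * (-dG)
            n_sup <- floor(energy / maint)
            active <- if (n_sup < n_alive) n_sup else n_alive
            if (n_sup > n_alive) {
              pool <- pool + (energy - n_alive * maint)
              births <- floor(pool / esyn)
              if (births > 0) {
                pool <- pool - births * esyn
                ring[(s %% ring_len) + 1L] <- ring[(s %% ring_len) + 1L] + births
                pop_nf <- pop_nf + births
              }
            }
            co2 <- co2 - x
            if (co2 < 0) co2 <- 0
            h2 <- h2 - 4 * x
            if (h2 < 0) h2 <- 0
            ch4 <- ch4 + x
            cum <- cum + x
          }
        }
      }
      ## (6) remove the cohort that has reached its life span
      idx <- ((s - life_steps) %% ring_len) + 1L
      dying <- ring[idx]
      if (dying > 0) {
        ring[idx] <- 0
        pop_nf <- pop_nf - dying
      }
      row <- c(s * dt, active, founders + pop_nf, co2, h2, ch4, x / dt, cum)
      if (anyNA(row) || any(!is.finite(row))) {
        stop(sprintf("non-finite reactor state at step %d", s))
      }
      out[s + 1L, ] <- row
    }
  }
  structure(list(series = as.data.frame(out), config = config, traits = traits,
                 thermo = thermo),
            class = "reactor_sim")
}

#' @export
print.reactor_sim <- function(x, ...) {
  n <- nrow(x$series) - 1L
  cat(sprintf("Vent reactor simulation: %d steps of %g s (%.3g s total)\n",
              n, x$config$dt, x$config$t_end))
  cat(sprintf("  inflows: CO2 %.3g, H2 %.3g mol/L/s; T = %g K\n",
              x$config$inflow_co2, x$config$inflow_h2, x$config$temperature))
  cat(sprintf("  final population %.4g (%.4g active), cumulative CH4 %.4g mol/L\n",
              x$series$population_total[n + 1L], x$series$population_active[n + 1L],
              x$series$cumulative_ch4[n + 1L]))
  invisible(x)
}

#' @export
summary.reactor_sim <- function(object, ...) {
  s <- object$series
  w <- min(object$config$averaging_window, object$config$t_end)
  out <- list(
    n_steps = nrow(s) - 1L,
    final_population = s$population_total[nrow(s)],
    peak_population = max(s$population_total),
    cumulative_ch4 = s$cumulative_ch4[nrow(s)],
    mean_production = if (w > 0) mean_production(object, w) else NA_real_,
    n_cycles = count_cycles(s$population_total)
  )
  class(out) <- "summary.reactor_sim"
  out
}

#' @export
print.summary.reactor_sim <- function(x, ...) {
  cat(sprintf("steps: %d  final pop: %.4g  peak pop: %.4g\n",
              x$n_steps, x$final_population, x$peak_population))
  cat(sprintf("cumulative CH4: %.4g mol/L  mean production: %.4g mol/L/s  cycles: %d\n",
              x$cumulative_ch4, x$mean_production, x$n_cycles))
  invisible(x)
}

#' @export
plot.reactor_sim <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$time_s, s$population_total, type = "l", log = "",
                 xlab = "time [s]", ylab = "cells", ...)
  graphics::lines(s$time_s, s$population_active, col = "grey50")
  graphics::legend("topright", legend = c("total", "active"),
                   col = c("black", "grey50"), lty = 1, bty = "n")
  graphics::matplot(s$time_s, cbind(s$conc_co2, s$conc_h2, s$conc_ch4),
                    type = "l", lty = 1, col = c("firebrick", "steelblue", "darkgreen"),
                    xlab = "time [s]", ylab = "conc [mol/L]")
  graphics::legend("topright", legend = c("CO2", "H2", "CH4"),
                   col = c("firebrick", "steelblue", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}

## count boom-crash cycles as upward crossings of the log-scale population
## midrange (cycles span orders of magnitude, so a linear midrange misses
## the repeated small booms after the initial transient)
count_cycles <- function(pop) {
  lp <- log(pmax(pop, 1))
  lo <- min(lp)
  hi <- max(lp)
  if (hi <= lo) return(0L)
  above <- lp > (lo + hi) / 2
  sum(diff(above) == 1L)
}

#' Time-averaged methane production
#'
#' Mean CH4 production rate over the final `window` seconds of a series:
#' (cumulative CH4 at the end minus cumulative CH4 at the window start)
#' divided by the window. Used to collapse limit-cycle trajectories to one
#' production figure per run.
#'
#' @param series A `reactor_sim` or `mock_series` object.
#' @param window Averaging window, s. Must not exceed the series span and
#'   must align with the time grid.
#' @return Mean production in mol/L/s.
#' @export
mean_production <- function(series, window) {
  UseMethod("mean_production")
}

mean_production_from_grid <- function(time, cumulative, window) {
  span <- time[length(time)] - time[1L]
  if (window > span + 1e-9) {
    stop("averaging window longer than the simulated series")
  }
  t_start <- time[length(time)] - window
  i <- which(abs(time - t_start) <= 1e-6 * max(1, abs(t_start)))
  if (length(i) != 1L) stop("window start does not align with the time grid")
  (cumulative[length(cumulative)] - cumulative[i]) / window
}

#' @export
mean_production.reactor_sim <- function(series, window = series$config$averaging_window) {
  mean_production_from_grid(series$series$time_s, series$series$cumulative_ch4, window)
}

#' @export
mean_production.mock_series <- function(series, window = NULL) {
  if (is.null(window)) window <- series$time[length(series$time)]
  mean_production_from_grid(series$time, series$cumulative, window)
}

#' Default logarithmic inflow axis
#'
#' 21 log-spaced inflow values covering 1e-12 to 1e-6 mol/L/s inclusive, the
#' standard sweep for both CO2 and H2; the full factorial sweep therefore
#' comprises 441 simulations.
#'
#' @param n Number of points.
#' @param lo,hi Endpoints, mol/L/s.
#' @return Numeric vector of inflows.
#' @export
default_inflow_axis <- function(n = 21, lo = 1e-12, hi = 1e-6) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Sweep a grid of substrate inflows
#'
#' Runs one reactor simulation per (CO2 inflow, H2 inflow) pair and records
#' the time-averaged methane production of each over the configured
#' averaging window. A failed simulation is recorded as `NA` with the reason
#' in the `flags` matrix rather than aborting the sweep.
#'
#' @param axis_co2,axis_h2 Strictly increasing positive inflow axes, mol/L/s.
#' @param config Template [reactor_config()]; its inflows are overridden.
#' @param traits An [organism_traits()].
#' @param thermo A [methanogenesis_thermo()].
#' @param verbose Emit a progress message per row.
#' @return An object of class `production_grid` with elements `axis_co2`,
#'   `axis_h2`, `mean_production` (matrix, CO2 inflow in rows), `n_cycles`
#'   and `flags`.
#' @export
run_grid <- function(axis_co2, axis_h2, config = reactor_config(),
                     traits = organism_traits(),
                     thermo = methanogenesis_thermo(), verbose = FALSE) {
  check_axis <- function(a, nm) {
    if (any(a <= 0) || any(diff(a) <= 0)) {
      stop(nm, " must be strictly increasing and positive")
    }
  }
  check_axis(axis_co2, "axis_co2")
  check_axis(axis_h2, "axis_h2")
  n1 <- length(axis_co2)
  n2 <- length(axis_h2)
  mp <- matrix(NA_real_, n1, n2)
  nc <- matrix(NA_integer_, n1, n2)
  fl <- matrix("", n1, n2)
  w <- config$averaging_window
  i_w <- NULL
  for (i in seq_len(n1)) {
    if (verbose) message(sprintf("grid row %d/%d (CO2 inflow %.3g mol/L/s)",
                                 i, n1, axis_co2[i]))
    for (j in seq_len(n2)) {
      cfg <- config
      cfg$inflow_co2 <- axis_co2[i]
      cfg$inflow_h2 <- axis_h2[j]
      res <- tryCatch({
        sim <- run_reactor(cfg, traits, thermo)
        ser <- sim$series
        in_window <- ser$time_s >= cfg$t_end - w - cfg$dt / 2
        list(mp = mean_production(sim, w),
             nc = count_cycles(ser$population_total[in_window]))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fl[i, j] <- conditionMessage(res)
      } else {
        mp[i, j] <- res$mp
        nc[i, j] <- res$nc
      }
    }
  }
  structure(list(axis_co2 = axis_co2, axis_h2 = axis_h2,
                 mean_production = mp, n_cycles = nc, flags = fl,
                 config = config, traits = traits),
            class = "production_grid")
}

#' @export
print.production_grid <- function(x, ...) {
  cat(sprintf("Production grid: %d x %d inflow pairs (%d simulations)\n",
              length(x$axis_co2), length(x$axis_h2),
              length(x$axis_co2) * length(x$axis_h2)))
  ok <- is.finite(x$mean_production)
  if (any(ok)) {
    cat(sprintf("  mean CH4 production: min %.3g, max %.3g mol/L/s\n",
                min(x$mean_production[ok]), max(x$mean_production[ok])))
  }
  if (any(!ok)) cat(sprintf("  %d failed cells flagged\n", sum(!ok)))
  invisible(x)
}

#' @export
as.data.frame.production_grid <- function(x, ...) {
  g <- expand.grid(inflow_co2_mol_per_l_s = x$axis_co2,
                   inflow_h2_mol_per_l_s = x$axis_h2,
                   KEEP.OUT.ATTRS = FALSE)
  g$mean_ch4_production_mol_per_l_s <- as.vector(x$mean_production)
  g$n_cycles_observed <- as.vector(x$n_cycles)
  g$flags <- as.vector(x$flags)
  g
}

#' @export
plot.production_grid <- function(x, ...) {
  graphics::image(log10(x$axis_co2), log10(x$axis_h2),
                  log10(pmax(x$mean_production, 1e-20)),
                  xlab = "log10 CO2 inflow [mol/L/s]",
                  ylab = "log10 H2 inflow [mol/L/s]",
                  main = "log10 mean CH4 production [mol/L/s]", ...)
  invisible(x)
}
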