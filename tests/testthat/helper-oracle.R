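# Independent brute-force evaluation of the reactor update rules, written
# directly from their prose description with naive data structures. Shares no
# code with the package; the standard reaction Gibbs energy and enthalpy are
# hand sums of the published formation values:
#   dG0 = (-34354 + 2*(-237183)) - (-385974 + 4*17723)   = -193638 J/mol
#   dH0 = (-87906 + 2*(-285830)) - (-413798 + 4*(-4200)) = -228968 J/mol
oracle_run <- function(n_steps,
                       co2 = 1e-3, h2 = 1e-2, ch4 = 2e-3,
                       inflow_co2 = 0, inflow_h2 = 0,
                       dt = 1000, temperature = 300, volume = 1,
                       maintenance_power = 5.32e-14,
                       max_metabolic_rate = 1.06e-18,
                       rate_constant = 2.88e-5,
                       life_span = 1e6,
                       synthesis_energy = 1e-11,
                       founders = 500) {
  R <- 8.314462618
  dG0_ref <- -193638
  dH0 <- -228968
  dG0T <- dH0 + (temperature / 298.15) * (dG0_ref - dH0)
  life_steps <- life_span / dt

  cohorts <- data.frame(birth = 0L, count = founders)
  pool <- 0
  cum <- 0
  rec <- data.frame(time_s = 0, population_active = 0,
                    population_total = founders, conc_co2 = co2,
                    conc_h2 = h2, conc_ch4 = ch4, inst_production = 0,
                    cumulative_ch4 = 0)
  for (s in seq_len(n_steps)) {
    co2 <- co2 + inflow_co2 * dt
    h2 <- h2 + inflow_h2 * dt
    n_alive <- sum(cohorts$count)
    x <- 0
    active <- 0
    if (co2 > 0 && h2 > 0) {
      dG <- dG0T + R * temperature * log(max(ch4, 1e-30) / (co2 * h2^4))
      if (dG < 0) {
        r_cell <- min(rate_constant * co2, max_metabolic_rate)
        x <- min(r_cell * n_alive * dt, co2, h2 / 4)
        energy <- x * volume * abs(dG)
        n_sup <- floor(energy / (maintenance_power * dt))
        active <- min(n_alive, n_sup)
        if (n_sup > n_alive) {
          pool <- pool + energy - n_alive * maintenance_power * dt
          births <- floor(pool / synthesis_energy)
          pool <- pool - births * synthesis_energy
          if (births > 0) {
            cohorts <- rbind(cohorts, data.frame(birth = s, count = births))
          }
        }
        co2 <- max(co2 - x, 0)
        h2 <- max(h2 - 4 * x, 0)
        ch4 <- ch4 + x
        cum <- cum + x
      }
    }
    cohorts <- cohorts[cohorts$birth == 0L | (s - cohorts$birth) < life_steps, ]
    rec <- rbind(rec, data.frame(time_s = s * dt, population_active = active,
                                 population_total = sum(cohorts$count),
                                 conc_co2 = co2, conc_h2 = h2, conc_ch4 = ch4,
                                 inst_production = x / dt,
                                 cumulative_ch4 = cum))
  }
  rec
}

# shorthand for a shortened-duration reactor configuration
short_config <- function(...) {
  reactor_config(t_end = 2e6, averaging_window = 1e6, ...)
}
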