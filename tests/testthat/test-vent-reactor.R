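test_that("single steps handle the gated, exhausted and founder-only regimes", {
  cfg <- reactor_config(inflow_co2 = 1e-15, inflow_h2 = 1e-15, t_end = 1e4)
  tr <- organism_traits()

  # CH4-saturated: substrates so depleted that dG >= 0, so only inflow acts
  st <- reactor_state(conc_co2 = 1e-9, conc_h2 = 1e-9, conc_ch4 = 2e-3)
  out <- reactor_step(st, cfg, tr)
  expect_equal(out$conc_co2, 1e-9 + 1e-15 * 1000)
  expect_equal(out$conc_h2, 1e-9 + 1e-15 * 1000)
  expect_equal(out$conc_ch4, 2e-3)
  expect_equal(out$active, 0)
  expect_equal(out$cumulative_ch4, 0)

  # substrate exhaustion: no CO2 and no inflow means no turnover, no births
  cfg0 <- reactor_config(t_end = 1e4, conc_co2 = 0)
  st <- reactor_state(conc_co2 = 0, cohort_count = 1e6)
  out <- reactor_step(st, cfg0, tr)
  expect_equal(out$conc_ch4, st$conc_ch4)
  expect_equal(out$active, 0)
  expect_identical(length(out$cohort_count), 1L)

  # founders only with abundant substrate: x = 500 r_max dt
  st <- reactor_state()
  out <- reactor_step(st, reactor_config(t_end = 1e4), tr)
  expect_equal(st$conc_co2 - out$conc_co2, 500 * 1.06e-18 * 1000)
  expect_equal(st$conc_h2 - out$conc_h2, 4 * 500 * 1.06e-18 * 1000)

  expect_error(reactor_step(reactor_state(conc_co2 = 1) |>
                              (\(s) { s$conc_h2 <- -1; s })(), cfg, tr),
               "invalid reactor state")
})

test_that("a zero-length run returns only the initial state", {
  sim <- run_reactor(reactor_config(t_end = 0))
  expect_identical(nrow(sim$series), 1L)
  expect_equal(sim$series$conc_co2, 1e-3)
  expect_equal(sim$series$population_total, 500)
})

test_that("run_reactor reproduces the independent brute-force oracle state by state", {
  for (inflows in list(c(0, 0), c(1e-9, 1e-9), c(1e-7, 1e-8))) {
    cfg <- reactor_config(inflow_co2 = inflows[1], inflow_h2 = inflows[2],
                          t_end = 1e4)
    sim <- run_reactor(cfg)
    oracle <- oracle_run(10, inflow_co2 = inflows[1], inflow_h2 = inflows[2])
    expect_equal(sim$series, oracle, tolerance = 1e-12)
  }
})

test_that("the fast stepper agrees with iterated reactor_step over many steps", {
  cfg <- reactor_config(inflow_co2 = 1e-8, inflow_h2 = 1e-8, t_end = 3e5)
  tr <- organism_traits()
  th <- methanogenesis_thermo()
  sim <- run_reactor(cfg, tr, th)
  st <- reactor_state(conc_co2 = cfg$conc_co2, conc_h2 = cfg$conc_h2,
                      conc_ch4 = cfg$conc_ch4,
                      cohort_count = tr$founder_population)
  for (s in seq_len(300)) st <- reactor_step(st, cfg, tr, th)
  last <- sim$series[301L, ]
  expect_equal(st$conc_co2, last$conc_co2, tolerance = 1e-12)
  expect_equal(st$conc_h2, last$conc_h2, tolerance = 1e-12)
  expect_equal(st$conc_ch4, last$conc_ch4, tolerance = 1e-12)
  expect_equal(sum(st$cohort_count), last$population_total, tolerance = 1e-12)
  expect_equal(st$cumulative_ch4, last$cumulative_ch4, tolerance = 1e-12)
})

test_that("carbon and hydrogen bookkeeping balance at every step", {
  for (inflows in list(c(1e-9, 1e-9), c(1e-7, 1e-12))) {
    cfg <- short_config(inflow_co2 = inflows[1], inflow_h2 = inflows[2])
    s <- run_reactor(cfg)$series
    supplied_co2 <- cfg$conc_co2 + cfg$inflow_co2 * s$time_s
    supplied_h2 <- cfg$conc_h2 + cfg$inflow_h2 * s$time_s
    # all consumed CO2 reappears as CH4 (no biomass carbon drawn)
    expect_lt(max(abs((supplied_co2 - s$conc_co2) - s$cumulative_ch4)), 1e-12)
    # 4 mol H2 per mol CH4, exactly
    expect_lt(max(abs((supplied_h2 - s$conc_h2) - 4 * s$cumulative_ch4)), 1e-12)
    # CH4 only accumulates
    expect_true(all(diff(s$conc_ch4) >= 0))
  }
})

test_that("windowed production is bounded by substrate supply", {
  cfg <- short_config(inflow_co2 = 1e-8, inflow_h2 = 1e-8)
  sim <- run_reactor(cfg)
  for (w in c(5e5, 1e6, 2e6)) {
    mp <- mean_production(sim, w)
    expect_lte(mp, (cfg$conc_co2 + cfg$inflow_co2 * cfg$t_end) / w)
    expect_lte(mp, (cfg$conc_h2 + cfg$inflow_h2 * cfg$t_end) / (4 * w))
  }
  expect_error(mean_production(sim, 1e7), "window longer")
})

test_that("the CO2-limited steady balance converts inflowing CO2 to methane", {
  # H2 inflow >= 4x CO2 inflow: long-run mean production within 20% of the
  # CO2 supply rate
  cfg <- reactor_config(inflow_co2 = 1e-9, inflow_h2 = 8e-9,
                        t_end = 5e7, averaging_window = 1e7)
  expect_equal(mean_production(run_reactor(cfg)), 1e-9, tolerance = 0.2)
})

test_that("mean production recovers sawtooth and constant-series means", {
  # constant production p over the window
  p <- 3.2e-9
  const <- structure(list(time = seq(0, 1e6, by = 1e3),
                          cumulative = p * seq(0, 1e6, by = 1e3)),
                     class = "mock_series")
  expect_equal(mean_production(const, 1e6), p)

  saw <- sawtooth_series(mean = 2e-8, period = 1e4, duration = 1e6, dt = 1e3)
  expect_equal(mean_production(saw), 2e-8, tolerance = 1e-6)

  # whole 10-step oracle run: cumulative CH4 / duration
  oracle <- oracle_run(10, inflow_co2 = 1e-9, inflow_h2 = 1e-9)
  sim <- run_reactor(reactor_config(inflow_co2 = 1e-9, inflow_h2 = 1e-9,
                                    t_end = 1e4))
  expect_equal(mean_production(sim, 1e4),
               oracle$cumulative_ch4[11] / 1e4, tolerance = 1e-12)
})

test_that("life span removals drive boom-crash cycles and founders persist", {
  # substrate-starved regime: the community booms on the accumulated stock,
  # crashes back to the founder cohort when its life span elapses, and
  # reboots once inflow has replenished the reactor
  cfg <- reactor_config(inflow_co2 = 1e-10, inflow_h2 = 1e-10,
                        t_end = 5e7, averaging_window = 1e7)
  s <- run_reactor(cfg)$series
  expect_true(all(s$population_total >= 500))
  expect_gt(count_cycles(s$population_total), 1)
  # the crash returns all the way to the immortal founder cohort
  expect_equal(min(s$population_total[-1]), 500)
  # life span must divide into time steps
  expect_error(run_reactor(cfg, organism_traits(life_span = 1500)),
               "integer multiple")
})

test_that("run_grid sweeps, bounds, and failure flagging behave", {
  cfg <- short_config()
  g11 <- run_grid(1e-9, 1e-9, cfg)
  # production cannot beat CO2 supply plus initial stock over the window
  bound <- (cfg$conc_co2 + 1e-9 * cfg$t_end) / cfg$averaging_window
  expect_lte(g11$mean_production[1, 1], max(1e-9, bound))
  expect_identical(dim(g11$mean_production), c(1L, 1L))

  a <- c(1e-10, 1e-8)
  b <- c(1e-9, 1e-8, 1e-7)
  g <- run_grid(a, b, cfg)
  expect_identical(dim(g$mean_production), c(2L, 3L))
  gs <- run_grid(b, a, cfg)
  expect_identical(dim(gs$mean_production), c(3L, 2L))
  # each cell corresponds to the single simulation with those inflows
  one <- run_reactor(short_config(inflow_co2 = a[2], inflow_h2 = b[1]))
  expect_equal(g$mean_production[2, 1], mean_production(one))

  expect_error(run_grid(c(1e-8, 1e-9), b, cfg), "strictly increasing")

  # a failing cell is flagged, not fatal: life span misaligned with dt
  bad <- run_grid(1e-9, 1e-9, cfg, organism_traits(life_span = 1500))
  expect_true(is.na(bad$mean_production[1, 1]))
  expect_match(bad$flags[1, 1], "integer multiple")
})

test_that("production in the inflow-limited regime is insensitive to temperature and cell cost", {
  base <- reactor_config(inflow_co2 = 1e-8, inflow_h2 = 1e-8,
                         t_end = 3e7, averaging_window = 1e7)
  ref <- mean_production(run_reactor(base))
  for (temp in c(325, 350)) {
    cfg <- base
    cfg$temperature <- temp
    expect_equal(mean_production(run_reactor(cfg)), ref, tolerance = 0.05)
  }
  for (esyn in c(1e-12, 1e-10)) {
    expect_equal(mean_production(run_reactor(base,
                                             organism_traits(synthesis_energy = esyn))),
                 ref, tolerance = 0.05)
  }
})
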