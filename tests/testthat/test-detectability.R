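# a bare-bones instrument with every ancillary noise term switched off,
# used to probe pure photon statistics
shot_only_instrument <- function(d = 10, iwa = 0.001) {
  instrument_spec(
    name = "shot", aperture_diameter = d,
    channels = data.frame(
      band_name = "VIS", lambda_min_um = 0.5, lambda_max_um = 1.0,
      resolving_power = 140, read_noise = 0, dark_noise = 0,
      optical_throughput = 0.2, iwa_value = iwa, iwa_unit = "lambda_over_d"),
    coronagraph_throughput = 0.5, raw_contrast = 0, exozodi_level = 0)
}

test_that("methane substitution rescales the other gases and renormalizes", {
  base <- archean_atmosphere()
  expect_equal(sum(base$mixing), 1)

  # identity when the requested fraction equals the baseline fraction
  same <- compose_atmosphere(base$mixing[["CH4"]], base)
  expect_equal(same$mixing, base$mixing)

  # raw-inventory arithmetic: N2 0.94 of a 1.00101 total with CH4 0.001
  out <- compose_atmosphere(0.01, base)
  expect_equal(out$mixing[["N2"]], 0.94 * (1 - 0.01) / (1.00101 - 0.001))
  expect_equal(out$mixing[["N2"]], 0.94 * 0.99 / 0.999, tolerance = 2e-3)

  for (f in c(0, 1e-4, 0.0025, 0.3)) {
    expect_equal(sum(compose_atmosphere(f, base)$mixing), 1)
    expect_equal(compose_atmosphere(f, base)$mixing[["CH4"]], f)
  }
  # ratios of the other gases to each other are preserved
  expect_equal(out$mixing[["CO2"]] / out$mixing[["N2"]],
               base$mixing[["CO2"]] / base$mixing[["N2"]])
  expect_error(compose_atmosphere(1), "\\[0, 1\\)")
})

test_that("stellar photon rates follow the inverse square law and Planck peak", {
  # constant-resolving-power bins spanning 0.2-2.0 um, as the instruments use
  edges <- 0.2 * (1 + 1 / 100)^(0:231)
  bins <- data.frame(lambda_min_um = edges[-length(edges)],
                     lambda_max_um = edges[-1])
  near <- star_photon_rate(scene(distance_pc = 5), bins)
  far <- star_photon_rate(scene(distance_pc = 10), bins)
  expect_equal(far, near / 4)

  # photon-count peak bin for a 5772 K Sun-like star lands just short of 1 um
  centre <- (bins$lambda_min_um + bins$lambda_max_um) / 2
  peak <- centre[which.max(near)]
  expect_gt(peak, 0.8)
  expect_lt(peak, 1.2)
  # per unit wavelength (uniform grid) the photon-count Planck peak moves to
  # ~3670 um K / T_eff
  uedges <- seq(0.2, 2.0, by = 0.01)
  ubins <- data.frame(lambda_min_um = uedges[-length(uedges)],
                      lambda_max_um = uedges[-1])
  urate <- star_photon_rate(scene(), ubins)
  upeak <- (ubins$lambda_min_um + ubins$lambda_max_um)[which.max(urate)] / 2
  expect_equal(upeak, 3670 / 5772, tolerance = 0.02)

  zero <- data.frame(lambda_min_um = 1, lambda_max_um = 1)
  expect_equal(star_photon_rate(scene(), zero), 0)
  expect_error(star_photon_rate(scene(),
                                data.frame(lambda_min_um = -1, lambda_max_um = 1)),
               "positive")
})

test_that("planet contrast has an exact continuum and closed-form band depths", {
  sc <- scene()
  empty <- band_library(list(), c(0.4, 2.0))
  flat <- planet_contrast(archean_atmosphere(), empty, sc, c(0.5, 1.0, 1.9))
  continuum <- 0.3 * (1 / pi) * (6.371e6 / 1.495978707e11)^2
  expect_equal(flat, rep(continuum, 3))

  # a single Gaussian band: depth at centre is exp(-2 N f sigma_peak)
  lib <- band_library(list(CH4 = data.frame(center_um = 1.2, width_um = 0.02,
                                            peak_m2 = 1e-27)),
                      c(0.4, 2.0))
  comp <- compose_atmosphere(0.0025)
  got <- planet_contrast(comp, lib, sc, 1.2)
  expect_equal(got, continuum * exp(-2 * column_density(comp) * 0.0025 * 1e-27))

  # more methane darkens band centres, leaves the continuum untouched
  lo <- planet_contrast(compose_atmosphere(5e-4), lib, sc, c(1.2, 0.6))
  hi <- planet_contrast(compose_atmosphere(0.01), lib, sc, c(1.2, 0.6))
  expect_lt(hi[1], lo[1])
  expect_equal(hi[2], lo[2])
})

test_that("the hydrostatic column density matches its defining formula", {
  base <- archean_atmosphere()
  expect_equal(column_density(base), 2.17e29, tolerance = 0.01)
  # halving the pressure halves the column
  half <- base
  half$surface_pressure_atm <- 0.5
  expect_equal(column_density(half), column_density(base) / 2)
})

test_that("observation counts follow the stated noise budget", {
  sc <- scene()
  comp <- compose_atmosphere(0.0025)

  # pure shot noise: N = sqrt(S) exactly
  obs <- observe(comp, shot_only_instrument(), sc)
  expect_equal(obs$noise, sqrt(obs$signal))

  # doubling the aperture: signal x4, noise x2, per-bin S/N x2
  obs2 <- observe(comp, shot_only_instrument(d = 20), sc)
  expect_equal(obs2$signal, 4 * obs$signal)
  expect_equal(obs2$noise, 2 * obs$noise)

  # one-channel chain check against hand-multiplied components
  inst <- habex_ss()
  full <- observe(comp, inst, sc)
  bins <- wavelength_bins(inst)
  star <- star_photon_rate(sc, bins)
  contrast <- planet_contrast(comp, default_band_library(), sc, bins$lambda_um)
  area <- pi * 2^2
  t_s <- 100 * 3600
  i <- which(bins$channel == "VIS")[1]
  thr <- 0.7 * 0.27
  c_p <- contrast[i] * star[i] * area * thr * t_s
  expect_equal(full$signal[i], c_p)
  var <- c_p + 1e-10 * star[i] * area * thr * t_s +
    4.5 * 5e-9 * area * t_s + 3e-5 * t_s + 0.008^2 * 360
  expect_equal(full$noise[i], sqrt(var))
})

test_that("the S/N statistic is a Pythagorean sum over shared bins", {
  mk <- function(lambda, signal, noise) {
    structure(list(lambda_um = lambda, channel = rep("VIS", length(lambda)),
                   contrast = rep(1e-10, length(lambda)), signal = signal,
                   noise = noise, iwa_pass = rep(TRUE, length(lambda))),
              class = "counts_spectrum")
  }
  base <- mk(c(0.6, 0.7), c(10, 20), c(1, 1))
  new <- mk(c(0.6, 0.7), c(13, 24), c(5, 5))  # noise of new is ignored
  expect_equal(snr(new, base), 5)
  expect_equal(snr(base, base), 0)
  # permuting bins consistently leaves the sum unchanged
  perm <- c(2, 1)
  base_p <- mk(c(0.7, 0.6), c(20, 10), c(1, 1))
  new_p <- mk(c(0.7, 0.6), c(24, 13), c(5, 5))
  expect_equal(snr(new_p, base_p), snr(new, base))
  expect_error(snr(mk(0.6, 1, 1), base), "identical wavelength bins")
})

test_that("detection time inverts the S/N quadratically from the 100 h anchor", {
  expect_identical(detection_time(5), 100)
  expect_equal(detection_time(10), 25)
  expect_equal(detection_time(5 / sqrt(2)), 200)
  expect_identical(detection_time(0), Inf)
  expect_identical(detection_time(-3), Inf)
})

test_that("mirror rescaling changes the aperture and nothing else", {
  a <- luvoir_a()
  expect_identical(rescale_mirror(a, 15), a)
  six <- rescale_mirror(a, 6)
  expect_equal(six$aperture_diameter, 6)
  expect_equal(six$coronagraph_throughput, 0.27)
  expect_equal(six$raw_contrast, 1e-10)
  expect_identical(six$channels, a$channels)
  # lambda/D IWAs re-evaluate: mas value scales as 1/D
  sc <- scene()
  expect_equal(iwa_check(six, sc, "VIS")$iwa_mas,
               iwa_check(a, sc, "VIS")$iwa_mas * 15 / 6)
  # fixed-mas starshade IWAs do not move
  h6 <- rescale_mirror(habex_ss(), 6)
  expect_equal(iwa_check(h6, sc, "NIR")$iwa_mas, 104)
  expect_error(rescale_mirror(a, -1), "positive")
})

test_that("inner-working-angle checks reproduce the worked geometries", {
  sc10 <- scene(distance_pc = 10)
  # 1 AU at 10 pc subtends 100 mas
  expect_equal(planet_separation_mas(sc10), 100)
  # HabEx starshade NIR: 104 mas IWA beats the 100 mas separation
  chk <- iwa_check(habex_ss(), sc10, "NIR")
  expect_false(chk$pass)
  expect_equal(chk$iwa_mas, 104)
  # LUVOIR A VIS at the 1.0 um channel edge: 4 lambda/D = 55 mas, passes
  chk <- iwa_check(luvoir_a(), sc10, "VIS")
  expect_true(chk$pass)
  expect_equal(chk$iwa_mas, 55, tolerance = 1e-3)
  expect_error(iwa_check(luvoir_a(), sc10, "UV"), "unknown channel")
})

test_that("IWA policies flag or mask an unreachable separation", {
  comp <- compose_atmosphere(0.0025)
  far <- scene(distance_pc = 25)  # 40 mas separation
  # starshade VIS IWA is 58 mas: nothing reachable
  obs <- observe(comp, habex_ss(), far)
  expect_false(attr(obs, "feasible"))
  expect_true(all(!obs$iwa_pass))
  res <- detect_methane(0.0025, habex_ss(), far)
  expect_false(res$feasible)
  expect_identical(res$t_5sigma, Inf)

  # masking zeroes excluded bins so they drop from the S/N
  sc10 <- scene(distance_pc = 10)
  masked <- observe(comp, habex_ss(), sc10, iwa_policy = "mask")
  expect_true(all(masked$signal[masked$channel == "NIR"] == 0))
  expect_true(all(masked$signal[masked$channel == "VIS"] > 0))
  r_mask <- detect_methane(0.0025, habex_ss(), sc10, iwa_policy = "mask")
  r_flag <- detect_methane(0.0025, habex_ss(), sc10)
  expect_lt(r_mask$snr, r_flag$snr)
})

test_that("wavelength bins tile each channel at its resolving power", {
  bins <- wavelength_bins(luvoir_b())
  expect_true(all(bins$lambda_min_um < bins$lambda_max_um))
  vis <- bins[bins$channel == "VIS", ]
  expect_equal(vis$lambda_max_um / vis$lambda_min_um,
               rep(1 + 1 / 140, nrow(vis)))
  expect_lte(max(vis$lambda_max_um), 1.0 + 1e-9)
  expect_gte(min(vis$lambda_min_um), 0.515)
  # bins are contiguous
  expect_equal(vis$lambda_min_um[-1], vis$lambda_max_um[-nrow(vis)])
})
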