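## physical constants (SI)
.H_PLANCK <- 6.62607015e-34
.C_LIGHT <- 2.99792458e8
.K_BOLTZ <- 1.380649e-23
.N_AVOGADRO <- 6.02214076e23
.R_SUN <- 6.957e8           # m
.R_EARTH <- 6.371e6         # m
.AU <- 1.495978707e11       # m
.PARSEC <- 3.0856775814913673e16  # m
.ATM <- 101325              # Pa
.G_SURF <- 9.81             # m/s2, Earth-like surface gravity
.MAS_PER_RAD <- 180 / pi * 3600 * 1e3

## fiducial zodiacal background count rate, photons/s/m2 per spectral bin,
## multiplied by the instrument's exozodi level; crude by design
.ZODI_FID <- 5e-9

## molar masses, kg/mol
.MOLAR_MASS <- c(N2 = 28.014e-3, CO2 = 44.01e-3, H2O = 18.015e-3,
                 CO = 28.01e-3, CH4 = 16.04e-3)

#' Archean-Earth-like baseline atmosphere
#'
#' Anoxic N2/CO2-dominated composition used as the planetary template: 94%
#' N2, 5% CO2, 1% H2O, 10 ppm CO and 0.1% CH4, normalized to sum exactly to
#' one, at 1 atm surface pressure and a flat 210 K temperature.
#'
#' @param f_ch4 Baseline methane fraction before normalization.
#' @return An object of class `atmosphere_composition`.
#' @export
archean_atmosphere <- function(f_ch4 = 0.001) {
  mix <- c(N2 = 0.94, CO2 = 0.05, H2O = 0.01, CO = 1e-5, CH4 = f_ch4)
  structure(list(mixing = mix / sum(mix), surface_pressure_atm = 1,
                 temperature_K = 210),
            class = "atmosphere_composition")
}

#' Reset the methane fraction of an atmosphere
#'
#' Sets CH4 to `f_ch4` and rescales every other gas by
#' (1 - f_ch4) / (1 - f_ch4_baseline), so the abundance ratios of the other
#' gases to each other are unchanged; the result is renormalized to sum to
#' one.
#'
#' @param f_ch4 New methane fraction, in \[0, 1).
#' @param baseline An `atmosphere_composition`.
#' @return An `atmosphere_composition`.
#' @examples
#' compose_atmosphere(0.01)$mixing["N2"]  # 0.94 x 0.99 / 0.999, renormalized
#' @export
compose_atmosphere <- function(f_ch4, baseline = archean_atmosphere()) {
  if (f_ch4 < 0 || f_ch4 >= 1) stop("f_ch4 must lie in [0, 1)")
  mix <- baseline$mixing
  f0 <- mix[["CH4"]]
  scale <- (1 - f_ch4) / (1 - f0)
  mix <- mix * scale
  mix[["CH4"]] <- f_ch4
  baseline$mixing <- mix / sum(mix)
  baseline
}

#' @export
print.atmosphere_composition <- function(x, ...) {
  cat(sprintf("Atmosphere at %g atm, %g K:\n", x$surface_pressure_atm,
              x$temperature_K))
  for (g in names(x$mixing)) cat(sprintf("  %-4s %.6g\n", g, x$mixing[[g]]))
  invisible(x)
}

#' Direct-imaging instrument description
#'
#' One coronagraph or starshade instrument: aperture, spectral channels with
#' their resolving power, detector noise and optical throughput, the
#' coronagraph (or starshade) throughput, the raw starlight-suppression
#' contrast, the inner working angle per channel (either a multiple of
#' lambda/D or a fixed angle in mas) and an exozodi level multiplying the
#' fiducial zodiacal background.
#'
#' @param name Instrument name.
#' @param aperture_diameter m.
#' @param channels Data frame with columns `band_name`, `lambda_min_um`,
#'   `lambda_max_um`, `resolving_power`, `read_noise`, `dark_noise`,
#'   `optical_throughput`, `iwa_value`, `iwa_unit` (`"lambda_over_d"` or
#'   `"mas"`); channels must be ordered and non-overlapping.
#' @param coronagraph_throughput Average suppression-system throughput.
#' @param raw_contrast Residual star light per unit star flux.
#' @param exozodi_level Dimensionless zodiacal multiplier.
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(name, aperture_diameter, channels,
                            coronagraph_throughput, raw_contrast,
                            exozodi_level = 4.5) {
  if (aperture_diameter <= 0) stop("aperture_diameter must be positive")
  need <- c("band_name", "lambda_min_um", "lambda_max_um", "resolving_power",
            "read_noise", "dark_noise", "optical_throughput", "iwa_value",
            "iwa_unit")
  if (!all(need %in% names(channels))) {
    stop("channels must have columns: ", paste(need, collapse = ", "))
  }
  if (is.unsorted(channels$lambda_min_um, strictly = TRUE) ||
      any(channels$lambda_max_um[-nrow(channels)] >
            channels$lambda_min_um[-1] + 1e-12)) {
    stop("channels must be ordered and non-overlapping")
  }
  if (any(channels$read_noise < 0) || any(channels$dark_noise < 0)) {
    stop("noise terms must be non-negative")
  }
  if (any(channels$optical_throughput <= 0 | channels$optical_throughput > 1) ||
      coronagraph_throughput <= 0 || coronagraph_throughput > 1) {
    stop("throughputs must lie in (0, 1]")
  }
  if (!all(channels$iwa_unit %in% c("lambda_over_d", "mas"))) {
    stop("iwa_unit must be 'lambda_over_d' or 'mas'")
  }
  structure(list(name = name, aperture_diameter = aperture_diameter,
                 channels = channels,
                 coronagraph_throughput = coronagraph_throughput,
                 raw_contrast = raw_contrast, exozodi_level = exozodi_level),
            class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("%s: D = %g m, T_cor = %g, raw contrast = %g, exozodi %g\n",
              x$name, x$aperture_diameter, x$coronagraph_throughput,
              x$raw_contrast, x$exozodi_level))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Proposed observatory concepts
#'
#' Instrument descriptions for the LUVOIR A (15 m), LUVOIR B (8 m) and
#' HabEx (4 m, with and without starshade) concepts. Only the visible and
#' near-infrared channels are carried: no methane bands are modelled below
#' 0.45 um, so the ultraviolet channels contribute nothing here.
#'
#' @return An `instrument_spec`.
#' @export
luvoir_a <- function() {
  instrument_spec(
    name = "LUVOIR A", aperture_diameter = 15,
    channels = data.frame(
      band_name = c("VIS", "NIR"),
      lambda_min_um = c(0.515, 1.0), lambda_max_um = c(1.0, 2.0),
      resolving_power = c(140, 70), read_noise = c(0, 2.5),
      dark_noise = c(3e-5, 0.002), optical_throughput = c(0.21, 0.3),
      iwa_value = c(4, 4), iwa_unit = c("lambda_over_d", "lambda_over_d")),
    coronagraph_throughput = 0.27, raw_contrast = 1e-10)
}

#' @rdname luvoir_a
#' @export
luvoir_b <- function() {
  instrument_spec(
    name = "LUVOIR B", aperture_diameter = 8,
    channels = data.frame(
      band_name = c("VIS", "NIR"),
      lambda_min_um = c(0.515, 1.0), lambda_max_um = c(1.0, 2.0),
      resolving_power = c(140, 70), read_noise = c(0, 2.5),
      dark_noise = c(3e-5, 0.002), optical_throughput = c(0.21, 0.3),
      iwa_value = c(3.5, 3.5), iwa_unit = c("lambda_over_d", "lambda_over_d")),
    coronagraph_throughput = 0.46, raw_contrast = 1e-10)
}

#' @rdname luvoir_a
#' @export
habex_ss <- function() {
  instrument_spec(
    name = "HabEx SS", aperture_diameter = 4,
    channels = data.frame(
      band_name = c("VIS", "NIR"),
      lambda_min_um = c(0.45, 0.975), lambda_max_um = c(0.975, 1.8),
      resolving_power = c(140, 40), read_noise = c(0.008, 0.32),
      dark_noise = c(3e-5, 0.005), optical_throughput = c(0.27, 0.36),
      iwa_value = c(58, 104), iwa_unit = c("mas", "mas")),
    coronagraph_throughput = 0.7, raw_contrast = 1e-10)
}

#' @rdname luvoir_a
#' @export
habex_no_ss <- function() {
  instrument_spec(
    name = "HabEx no SS", aperture_diameter = 4,
    channels = data.frame(
      band_name = c("VIS", "NIR"),
      lambda_min_um = c(0.45, 0.975), lambda_max_um = c(0.975, 1.8),
      resolving_power = c(140, 40), read_noise = c(0.008, 0.32),
      dark_noise = c(3e-5, 0.005), optical_throughput = c(0.15, 0.15),
      iwa_value = c(2.5, 2.5), iwa_unit = c("lambda_over_d", "lambda_over_d")),
    coronagraph_throughput = 0.55, raw_contrast = 2.5e-10)
}

#' All four standard instrument concepts
#'
#' @return Named list of [instrument_spec()] objects.
#' @export
standard_instruments <- function() {
  list("LUVOIR A" = luvoir_a(), "LUVOIR B" = luvoir_b(),
       "HabEx SS" = habex_ss(), "HabEx no SS" = habex_no_ss())
}

#' Rescale an instrument's primary mirror
#'
#' Changes only the aperture diameter; all throughputs, detector noise
#' terms, the raw contrast and the IWA definitions are retained (lambda/D
#' IWAs therefore re-evaluate at the new diameter, fixed-mas IWAs are
#' unchanged). A real redesign would of course change more than the mirror;
#' this mirrors the deliberately rough 6 m what-if comparison.
#'
#' @param instrument An [instrument_spec()].
#' @param new_diameter m (> 0).
#' @return The rescaled `instrument_spec`, with " (X m)" noted in the name
#'   when the diameter changed.
#' @export
rescale_mirror <- function(instrument, new_diameter) {
  if (new_diameter <= 0) stop("new_diameter must be positive")
  if (new_diameter != instrument$aperture_diameter) {
    instrument$name <- sprintf("%s (%g m)", instrument$name, new_diameter)
  }
  instrument$aperture_diameter <- new_diameter
  instrument
}

#' Star-planet-observer viewing geometry
#'
#' A Sun-like host observed at the planet's maximum elongation (quadrature),
#' so the projected star-planet separation equals the orbital distance.
#'
#' @param distance_pc Observer distance, pc.
#' @param star_teff Stellar effective temperature, K.
#' @param star_radius_rsun Stellar radius, solar radii.
#' @param planet_radius_rearth Planet radius, Earth radii.
#' @param orbital_distance_au Orbital distance, AU.
#' @param geometric_albedo Continuum geometric albedo.
#' @param exposure_time_h Exposure time, h.
#' @return An object of class `scene`.
#' @export
scene <- function(distance_pc = 10, star_teff = 5772, star_radius_rsun = 1,
                  planet_radius_rearth = 1, orbital_distance_au = 1,
                  geometric_albedo = 0.3, exposure_time_h = 100) {
  vals <- c(distance_pc, star_teff, star_radius_rsun, planet_radius_rearth,
            orbital_distance_au, geometric_albedo, exposure_time_h)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scene parameters must be positive and finite")
  }
  structure(list(distance_pc = distance_pc, star_teff = star_teff,
                 star_radius_rsun = star_radius_rsun,
                 planet_radius_rearth = planet_radius_rearth,
                 orbital_distance_au = orbital_distance_au,
                 geometric_albedo = geometric_albedo,
                 exposure_time_h = exposure_time_h),
            class = "scene")
}

#' Planet angular separation at quadrature
#'
#' @param scene A [scene()].
#' @return Separation in milliarcseconds (1 AU at 1 pc = 1000 mas).
#' @export
planet_separation_mas <- function(scene) {
  1000 * scene$orbital_distance_au / scene$distance_pc
}

#' Per-channel wavelength bins
#'
#' Half-open bins of constant resolving power (width lambda / R), built
#' multiplicatively from the channel's lower edge; the last bin is the final
#' one wholly inside the channel. Bin centres are the arithmetic midpoints.
#'
#' @param instrument An [instrument_spec()].
#' @return Data frame with `channel`, `lambda_min_um`, `lambda_max_um`,
#'   `lambda_um` (centre).
#' @export
wavelength_bins <- function(instrument) {
  out <- lapply(seq_len(nrow(instrument$channels)), function(i) {
    ch <- instrument$channels[i, ]
    edges <- ch$lambda_min_um
    while (edges[length(edges)] * (1 + 1 / ch$resolving_power) <=
             ch$lambda_max_um + 1e-12) {
      edges <- c(edges, edges[length(edges)] * (1 + 1 / ch$resolving_power))
    }
    if (length(edges) < 2L) return(NULL)
    data.frame(channel = ch$band_name,
               lambda_min_um = edges[-length(edges)],
               lambda_max_um = edges[-1],
               lambda_um = (edges[-length(edges)] + edges[-1]) / 2)
  })
  do.call(rbind, out)
}

#' Stellar photon rate at the observer
#'
#' Blackbody photon radiance of the host star diluted to the observer:
#' pi B_phot(lambda, T_eff) (R_star / d)^2 integrated over each bin
#' (midpoint rule), in photons per second per square metre of collecting
#' area per bin.
#'
#' @param scene A [scene()].
#' @param bins Data frame with `lambda_min_um` and `lambda_max_um` columns
#'   (zero-width bins give zero counts).
#' @return Photons/s/m2 per bin.
#' @export
star_photon_rate <- function(scene, bins) {
  lam_lo <- bins$lambda_min_um * 1e-6
  lam_hi <- bins$lambda_max_um * 1e-6
  if (any(lam_lo <= 0) || any(lam_hi < lam_lo)) {
    stop("bins must be positive and increasing")
  }
  lam <- (lam_lo + lam_hi) / 2
  ## Planck photon radiance, photons/s/m2/sr/m
  b <- 2 * .C_LIGHT / lam^4 / expm1(.H_PLANCK * .C_LIGHT /
                                      (lam * .K_BOLTZ * scene$star_teff))
  dilution <- (scene$star_radius_rsun * .R_SUN /
                 (scene$distance_pc * .PARSEC))^2
  pi * b * dilution * (lam_hi - lam_lo)
}

#' Hydrostatic molecular column density
#'
#' N_col = P N_A / (m_bar g): total molecules per square metre of an
#' isothermal column at surface pressure P with mean molar mass m_bar from
#' the composition and Earth-like surface gravity. About 2.17e29 /m2 for the
#' baseline atmosphere at 1 atm.
#'
#' @param composition An `atmosphere_composition`.
#' @return Column density, molecules/m2.
#' @export
column_density <- function(composition) {
  mm <- .MOLAR_MASS[names(composition$mixing)]
  if (anyNA(mm)) stop("unknown gas in composition: ",
                      paste(names(composition$mixing)[is.na(mm)], collapse = ", "))
  mbar <- sum(composition$mixing * mm)
  composition$surface_pressure_atm * .ATM * .N_AVOGADRO / (mbar * .G_SURF)
}

#' Planet-to-star contrast spectrum
#'
#' Two-pass Beer-Lambert slab on top of a grey Lambert reflector:
#' contrast(lambda) = A_g Phi (R_p / a)^2 exp(-2 N_col sum_g f_g
#' sigma_g(lambda)), with the quadrature Lambert phase factor Phi = 1 / pi.
#' The continuum (absorber-free) value is exact; band depths come from the
#' Gaussian band library.
#'
#' @param composition An `atmosphere_composition`.
#' @param bands A [band_library()].
#' @param scene A [scene()].
#' @param lambda_um Wavelengths, um, within the library validity range.
#' @return Dimensionless planet/star flux ratio at each wavelength.
#' @export
planet_contrast <- function(composition, bands, scene, lambda_um) {
  continuum <- scene$geometric_albedo * (1 / pi) *
    (scene$planet_radius_rearth * .R_EARTH /
       (scene$orbital_distance_au * .AU))^2
  ncol_tot <- column_density(composition)
  tau <- numeric(length(lambda_um))
  for (g in names(composition$mixing)) {
    f <- composition$mixing[[g]]
    if (f > 0) tau <- tau + f * cross_section(bands, g, lambda_um)
  }
  continuum * exp(-2 * ncol_tot * tau)
}

#' Inner-working-angle check for one channel
#'
#' Compares the planet's angular separation at quadrature with the channel's
#' inner working angle; lambda/D IWAs are evaluated conservatively at the
#' channel's red (long-wavelength) edge, fixed-mas IWAs as given.
#'
#' @param instrument An [instrument_spec()].
#' @param scene A [scene()].
#' @param channel Channel band name or row index.
#' @return List with `pass`, `separation_mas`, `iwa_mas`.
#' @examples
#' iwa_check(habex_ss(), scene(distance_pc = 10), "NIR")  # 104 vs 100 mas: fail
#' @export
iwa_check <- function(instrument, scene, channel) {
  ch <- if (is.character(channel)) {
    instrument$channels[instrument$channels$band_name == channel, ]
  } else {
    instrument$channels[channel, ]
  }
  if (nrow(ch) != 1L) stop("unknown channel")
  sep <- planet_separation_mas(scene)
  iwa_mas <- if (ch$iwa_unit == "mas") {
    ch$iwa_value
  } else {
    ch$iwa_value * ch$lambda_max_um * 1e-6 / instrument$aperture_diameter *
      .MAS_PER_RAD
  }
  list(pass = sep >= iwa_mas, separation_mas = sep, iwa_mas = iwa_mas)
}

## per-bin IWA in mas for a channel row (vectorized over lambda)
bin_iwa_mas <- function(ch, lambda_um, aperture) {
  if (ch$iwa_unit == "mas") {
    rep(ch$iwa_value, length(lambda_um))
  } else {
    ch$iwa_value * lambda_um * 1e-6 / aperture * .MAS_PER_RAD
  }
}

#' Simulate a photon-counting observation
#'
#' Builds the per-bin signal and 1-sigma noise counts of a 100 h-class
#' direct-imaging observation: planet counts C_p = contrast x star rate x
#' collecting area x coronagraph and optical throughput x time, starlight
#' leak C_l at the raw contrast through the same chain, a zodiacal term
#' C_z = exozodi x zeta_fid x area x time, dark current, and read noise
#' accumulated over 1000 s frames. Noise is
#' sqrt(C_p + C_l + C_z + dark t + read^2 n_frames).
#'
#' IWA handling (`iwa_policy`): `"flag"` (default) records per-bin and
#' per-channel IWA status and flags overall feasibility (the planet must be
#' outside the IWA somewhere in at least one channel) but integrates every
#' bin, matching how the published instrument comparisons treat marginal
#' separations; `"mask"` additionally zeroes out bins (lambda/D IWAs) or
#' whole channels (fixed-mas IWAs) that the IWA excludes.
#'
#' @param composition An `atmosphere_composition`.
#' @param instrument An [instrument_spec()].
#' @param scene A [scene()].
#' @param bands A [band_library()].
#' @param iwa_policy `"flag"` or `"mask"`.
#' @return An object of class `counts_spectrum`: data-frame-like list with
#'   `lambda_um`, `channel`, `contrast`, `signal`, `noise`, `iwa_pass`, and
#'   attributes `feasible` and `meta`.
#' @export
observe <- function(composition, instrument, scene,
                    bands = default_band_library(),
                    iwa_policy = c("flag", "mask")) {
  iwa_policy <- match.arg(iwa_policy)
  bins <- wavelength_bins(instrument)
  t_s <- scene$exposure_time_h * 3600
  area <- pi * (instrument$aperture_diameter / 2)^2
  star <- star_photon_rate(scene, bins)
  contrast <- planet_contrast(composition, bands, scene, bins$lambda_um)

  sep <- planet_separation_mas(scene)
  n_frames <- ceiling(t_s / 1000)

  chs <- instrument$channels
  sig <- noise <- numeric(nrow(bins))
  iwa_pass <- logical(nrow(bins))
  ch_feasible <- logical(nrow(chs))
  for (i in seq_len(nrow(chs))) {
    ch <- chs[i, ]
    idx <- bins$channel == ch$band_name
    thr <- instrument$coronagraph_throughput * ch$optical_throughput
    c_p <- contrast[idx] * star[idx] * area * thr * t_s
    c_l <- instrument$raw_contrast * star[idx] * area * thr * t_s
    c_z <- instrument$exozodi_level * .ZODI_FID * area * t_s
    var <- c_p + c_l + c_z + ch$dark_noise * t_s + ch$read_noise^2 * n_frames
    pass <- sep >= bin_iwa_mas(ch, bins$lambda_um[idx],
                               instrument$aperture_diameter)
    ch_feasible[i] <- any(pass)
    if (iwa_policy == "mask") {
      c_p[!pass] <- 0
      var[!pass] <- Inf
    }
    sig[idx] <- c_p
    noise[idx] <- sqrt(var)
    iwa_pass[idx] <- pass
  }
  structure(list(lambda_um = bins$lambda_um, channel = bins$channel,
                 contrast = contrast, signal = sig, noise = noise,
                 iwa_pass = iwa_pass),
            feasible = any(ch_feasible),
            meta = list(instrument = instrument$name,
                        aperture_m = instrument$aperture_diameter,
                        distance_pc = scene$distance_pc,
                        exposure_time_h = scene$exposure_time_h,
                        f_ch4 = composition$mixing[["CH4"]],
                        iwa_policy = iwa_policy,
                        separation_mas = sep),
            class = "counts_spectrum")
}

#' @export
print.counts_spectrum <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Counts spectrum: %s at %g pc, %g h, CH4 %.4g\n",
              m$instrument, m$distance_pc, m$exposure_time_h, m$f_ch4))
  cat(sprintf("  %d bins, feasible: %s\n", length(x$lambda_um),
              attr(x, "feasible")))
  invisible(x)
}

#' @export
as.data.frame.counts_spectrum <- function(x, ...) {
  data.frame(lambda_um = x$lambda_um, channel = x$channel,
             contrast = x$contrast, signal_counts = x$signal,
             noise_counts = x$noise, iwa_pass = x$iwa_pass)
}

#' @export
plot.counts_spectrum <- function(x, ...) {
  graphics::plot(x$lambda_um, x$contrast, type = "l",
                 xlab = "wavelength [um]", ylab = "planet/star contrast", ...)
  invisible(x)
}

#' Integrated signal-to-noise of a methane difference spectrum
#'
#' S/N = sqrt(sum_i ((S_i_new - S_i_base) / N_i)^2) over all shared bins,
#' with the noise taken from the baseline observation, so identical inputs
#' give exactly zero. Bins the IWA excluded under the `"mask"` policy carry
#' infinite noise and so drop out of the sum.
#'
#' @param obs_new,obs_base `counts_spectrum` objects on identical bins.
#' @return Non-negative S/N.
#' @export
snr <- function(obs_new, obs_base) {
  if (length(obs_new$lambda_um) != length(obs_base$lambda_um) ||
      any(abs(obs_new$lambda_um - obs_base$lambda_um) > 1e-12)) {
    stop("observations are not on identical wavelength bins")
  }
  term <- (obs_new$signal - obs_base$signal) / obs_base$noise
  term[!is.finite(term)] <- 0
  sqrt(sum(term^2))
}

#' Time to a 5-sigma detection
#'
#' t = reference x (5 / snr)^2: the exposure needed to scale the integrated
#' S/N of the reference exposure up to 5, assuming photon-dominated
#' statistics. `snr <= 0` returns `Inf` (the infeasible sentinel).
#'
#' @param snr Integrated S/N achieved in the reference exposure.
#' @param reference_exposure h.
#' @return Hours.
#' @examples
#' detection_time(5)   # 100 h
#' detection_time(10)  # 25 h
#' @export
detection_time <- function(snr, reference_exposure = 100) {
  ifelse(snr > 0, reference_exposure * (5 / snr)^2, Inf)
}

#' End-to-end methane detectability for one instrument and scene
#'
#' Composes the elevated-methane and baseline atmospheres, observes both,
#' and reduces to the integrated S/N and the 5-sigma detection time.
#'
#' @param f_ch4 Methane fraction of the candidate atmosphere.
#' @param instrument An [instrument_spec()].
#' @param scene A [scene()].
#' @param baseline_ch4 Methane fraction of the reference atmosphere the
#'   difference spectrum is formed against. The default 0.05% is the highest
#'   methane level not requiring a biological source; 0.1% reproduces the
#'   alternative plain-template baseline.
#' @param bands A [band_library()].
#' @param iwa_policy Passed to [observe()].
#' @return An object of class `detection_result` with `snr`, `t_5sigma`
#'   (h) and `feasible`.
#' @export
detect_methane <- function(f_ch4, instrument, scene = ventmethane::scene(),
                           baseline_ch4 = 0.0005,
                           bands = default_band_library(),
                           iwa_policy = c("flag", "mask")) {
  iwa_policy <- match.arg(iwa_policy)
  obs_base <- observe(compose_atmosphere(baseline_ch4), instrument, scene,
                      bands, iwa_policy)
  obs_new <- observe(compose_atmosphere(f_ch4), instrument, scene,
                     bands, iwa_policy)
  s <- snr(obs_new, obs_base)
  feasible <- attr(obs_base, "feasible") && attr(obs_new, "feasible")
  structure(list(snr = s,
                 t_5sigma = if (feasible) detection_time(s, scene$exposure_time_h) else Inf,
                 feasible = feasible),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("S/N = %.3g, t(5 sigma) = %.4g h, feasible: %s\n",
              x$snr, x$t_5sigma, x$feasible))
  invisible(x)
}
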