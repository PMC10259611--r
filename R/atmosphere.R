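## seconds in a 365-day year; the <0.2% difference from a Julian or tropical
## year is far below the rounding carried by the flux chain
.SECONDS_PER_YEAR <- 3.1536e7

## denominator of the linear flux-to-mixing-ratio relation, Tmol/yr; the
## extra factor 3 corrects the diffusion-limited balance for unmodelled sinks
.MIXING_RATIO_DENOM <- 3 * 6680

#' Ocean-floor vent coverage model
#'
#' Geometry and transport factors that scale per-litre methane production in
#' a vent bioreactor to a global atmospheric flux: total ocean-floor area, a
#' mean vent height (so coverage fraction x area x height is the global vent
#' fluid volume), the fraction of produced methane that escapes oxidation and
#' reaches the atmosphere (eta: 1 "best", 0.2 "conservative"), and a flat
#' abiotic methane flux added before biogenicity is judged.
#'
#' The default ocean area is 3.62e7 km2, the value the headline coverage
#' results are arithmetically consistent with; `ocean_area_preset = "census"`
#' selects 3.62e8 km2, the value in the underlying hypsometry source and the
#' one consistent with the modern-Earth vent census. The two differ by a
#' factor of ten and cannot both be right; both are provided.
#'
#' @param ocean_area km2.
#' @param vent_height m.
#' @param outgassing_fraction Fraction of produced CH4 reaching the
#'   atmosphere, in (0, 1].
#' @param abiotic_flux Tmol/yr of non-biological methane.
#' @param ocean_area_preset `"headline"` (3.62e7 km2, default) or `"census"`
#'   (3.62e8 km2); ignored if `ocean_area` is given explicitly.
#' @return An object of class `vent_coverage_model`.
#' @export
vent_coverage_model <- function(ocean_area = NULL, vent_height = 10,
                                outgassing_fraction = 1, abiotic_flux = 10,
                                ocean_area_preset = c("headline", "census")) {
  if (is.null(ocean_area)) {
    ocean_area <- switch(match.arg(ocean_area_preset),
                         headline = 3.62e7, census = 3.62e8)
  }
  if (ocean_area <= 0 || vent_height <= 0) {
    stop("ocean_area and vent_height must be positive")
  }
  if (outgassing_fraction <= 0 || outgassing_fraction > 1) {
    stop("outgassing_fraction must lie in (0, 1]")
  }
  if (abiotic_flux < 0) stop("abiotic_flux must be non-negative")
  structure(list(ocean_area = ocean_area, vent_height = vent_height,
                 outgassing_fraction = outgassing_fraction,
                 abiotic_flux = abiotic_flux),
            class = "vent_coverage_model")
}

#' Global hydrothermal vent fluid volume
#'
#' Volume of vent bioreactor fluid implied by a fractional ocean-floor
#' coverage: coverage x area x vent height, in litres (1 km2 x 1 m = 1e9 L).
#'
#' @param coverage_fraction Fraction of the ocean floor covered, in \[0, 1\].
#' @param ocean_area km2.
#' @param vent_height m.
#' @return Volume in L.
#' @examples
#' vent_volume(1, 3.62e7, 10)  # 3.62e17 L at full coverage
#' @export
vent_volume <- function(coverage_fraction, ocean_area = 3.62e7, vent_height = 10) {
  if (any(coverage_fraction < 0 | coverage_fraction > 1)) {
    stop("coverage_fraction must lie in [0, 1]")
  }
  coverage_fraction * ocean_area * vent_height * 1e9
}

#' Global methane flux from vent production
#'
#' Scales a per-litre production rate to a global biotic flux over the given
#' vent volume, applies the outgassing fraction, and adds the abiotic floor:
#' F_bio = rate x volume x s/yr / 1e12 (Tmol/yr); F_total = eta F_bio +
#' abiotic.
#'
#' @param production_rate mol/L/s (>= 0).
#' @param volume Vent fluid volume, L.
#' @param outgassing_fraction eta in (0, 1].
#' @param abiotic_flux Tmol/yr.
#' @return A list of class `flux_result` with `biotic_flux`, `total_flux`
#'   (Tmol/yr) and `mixing_ratio` (fraction).
#' @export
global_flux <- function(production_rate, volume, outgassing_fraction = 1,
                        abiotic_flux = 10) {
  if (any(production_rate < 0)) stop("production_rate must be non-negative")
  f_bio <- production_rate * volume * .SECONDS_PER_YEAR / 1e12
  f_tot <- outgassing_fraction * f_bio + abiotic_flux
  structure(list(biotic_flux = f_bio, total_flux = f_tot,
                 mixing_ratio = mixing_ratio(f_tot)),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("CH4 flux: biotic %.4g, total %.4g Tmol/yr -> mixing ratio %.4g (%.3g%%)\n",
              x$biotic_flux, x$total_flux, x$mixing_ratio, 100 * x$mixing_ratio))
  invisible(x)
}

#' Atmospheric methane mixing ratio from a global flux
#'
#' Linear flux-to-mixing-ratio relation for an anoxic Archean-like
#' atmosphere, f = F / (3 x 6680) with F in Tmol/yr; the factor 1/3 corrects
#' the underlying diffusion-limited hydrogen-balance estimate for methane
#' sinks it neglects. A 10 Tmol/yr flux maps to about 0.05% methane,
#' 50 Tmol/yr to 0.25% and 200 Tmol/yr to 1%.
#'
#' @param total_flux Tmol/yr (>= 0).
#' @return Mixing ratio as a dimensionless fraction.
#' @examples
#' 100 * mixing_ratio(c(10, 50, 200))  # percent
#' @export
mixing_ratio <- function(total_flux) {
  if (any(total_flux < 0)) stop("total_flux must be non-negative")
  total_flux / .MIXING_RATIO_DENOM
}

#' Invert the flux chain for the required vent coverage
#'
#' Closed-form inversion of the linear chain production rate -> volume ->
#' flux -> mixing ratio: the ocean-floor coverage fraction needed to reach a
#' target methane mixing ratio at a given per-litre production rate. If the
#' abiotic flux alone reaches the target, returns 0 with a warning flag; if
#' more than complete coverage would be required, the value > 1 is returned
#' with an `infeasible` flag rather than clipped.
#'
#' @param production_rate mol/L/s (> 0).
#' @param f_target Target mixing ratio, fraction.
#' @param model A [vent_coverage_model()].
#' @return Coverage fraction, with attribute `flag` equal to `""`,
#'   `"abiotic_sufficient"` or `"infeasible"`.
#' @examples
#' coverage_for_mixing(9.97e-7, 0.0025)  # about 3.5e-6 (3.5e-4 %)
#' @export
coverage_for_mixing <- function(production_rate, f_target,
                                model = vent_coverage_model()) {
  if (any(production_rate <= 0)) stop("production_rate must be positive")
  f_abiotic <- mixing_ratio(model$abiotic_flux)
  flux_needed <- f_target * .MIXING_RATIO_DENOM - model$abiotic_flux
  if (any(flux_needed < 0)) {
    warning("target mixing ratio is reached by the abiotic flux alone")
    flux_needed <- pmax(flux_needed, 0)
  }
  vol_per_cov <- model$ocean_area * model$vent_height * 1e9
  cov <- flux_needed * 1e12 /
    (model$outgassing_fraction * production_rate * vol_per_cov * .SECONDS_PER_YEAR)
  flag <- ifelse(f_target <= f_abiotic, "abiotic_sufficient",
                 ifelse(cov > 1, "infeasible", ""))
  attr(cov, "flag") <- flag
  cov
}

#' Invert the flux chain for the required production rate
#'
#' Exact algebraic inverse partner of [coverage_for_mixing()]: the per-litre
#' production rate needed to reach a target mixing ratio at a given coverage.
#'
#' @param coverage_fraction Coverage fraction (> 0).
#' @param f_target Target mixing ratio, fraction.
#' @param model A [vent_coverage_model()].
#' @return Production rate in mol/L/s, with attribute `flag` as in
#'   [coverage_for_mixing()].
#' @export
rate_for_mixing <- function(coverage_fraction, f_target,
                            model = vent_coverage_model()) {
  if (any(coverage_fraction <= 0)) stop("coverage_fraction must be positive")
  f_abiotic <- mixing_ratio(model$abiotic_flux)
  flux_needed <- f_target * .MIXING_RATIO_DENOM - model$abiotic_flux
  if (any(flux_needed < 0)) {
    warning("target mixing ratio is reached by the abiotic flux alone")
    flux_needed <- pmax(flux_needed, 0)
  }
  vol <- coverage_fraction * model$ocean_area * model$vent_height * 1e9
  rate <- flux_needed * 1e12 /
    (model$outgassing_fraction * vol * .SECONDS_PER_YEAR)
  attr(rate, "flag") <- ifelse(f_target <= f_abiotic, "abiotic_sufficient", "")
  rate
}

#' Classify a methane mixing ratio for biogenicity
#'
#' Half-open bins at the 0.05% (abiotic/biogenic threshold), 0.25% (likely
#' biogenic) and 1% (very likely biogenic) methane levels.
#'
#' @param f Mixing ratio fraction (>= 0).
#' @return Character vector with levels `below_threshold`, `threshold`,
#'   `likely_biogenic`, `very_likely_biogenic`.
#' @export
classify_mixing_ratio <- function(f) {
  if (any(f < 0)) stop("mixing ratio must be non-negative")
  cut(f, breaks = c(-Inf, 0.0005, 0.0025, 0.01, Inf), right = FALSE,
      labels = c("below_threshold", "threshold", "likely_biogenic",
                 "very_likely_biogenic")) |> as.character()
}

#' Modern-Earth hydrothermal vent coverage
#'
#' Percentage of the ocean floor covered by vents for a census of `n_vents`
#' vents of `area_per_vent` square metres each.
#'
#' @param n_vents Number of vents.
#' @param area_per_vent m2 per vent.
#' @param ocean_area km2.
#' @return Coverage in percent.
#' @examples
#' modern_earth_coverage(8000, 100, 3.62e8)  # about 2.2e-7 %
#' @export
modern_earth_coverage <- function(n_vents, area_per_vent, ocean_area) {
  if (any(c(n_vents, area_per_vent, ocean_area) <= 0)) {
    stop("all inputs must be positive")
  }
  100 * n_vents * area_per_vent / (ocean_area * 1e6)
}

#' Vents implied by a ridge survey
#'
#' Scales a surveyed vent density (vents per km of ridge) to a total ridge
#' length. Takes density and length as explicit inputs because published
#' census figures disagree with their own inputs; this helper takes no side.
#'
#' @param vents_per_km Vents per km of surveyed ridge.
#' @param ridge_length_km Total ridge length, km.
#' @return Estimated number of vents.
#' @export
vent_census <- function(vents_per_km, ridge_length_km) {
  if (any(c(vents_per_km, ridge_length_km) <= 0)) stop("inputs must be positive")
  vents_per_km * ridge_length_km
}
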