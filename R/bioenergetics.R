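#' @keywords internal
"_PACKAGE"

## Universal gas constant, J/mol/K
.R_GAS <- 8.314462618

#' Read a plain-text key-value table
#'
#' Parses the two-column tab-separated key-value format used for the shipped
#' thermodynamic constants and for serialized band libraries. Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the file.
#' @return A named numeric vector.
#' @export
read_key_value <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed key-value line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(vals)) stop("non-numeric value for key(s): ",
                        paste(keys[is.na(vals)], collapse = ", "))
  stats::setNames(vals, keys)
}

#' Write a plain-text key-value table
#'
#' @param x Named numeric vector.
#' @param path Output path.
#' @param header Optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_key_value <- function(x, path, header = NULL) {
  stopifnot(is.numeric(x), !is.null(names(x)), all(nzchar(names(x))))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("%s\t%.17g", names(x), unname(x)), con)
  invisible(path)
}

#' Thermodynamics of hydrogenotrophic methanogenesis
#'
#' Builds the reaction-thermodynamics descriptor for the catabolic reaction
#' CO2 + 4 H2 -> CH4 + 2 H2O that powers the methanogens in the vent
#' reactor. The standard Gibbs energy and enthalpy of reaction are assembled
#' from the standard-state formation properties shipped with the package
#' (aqueous CO2, H2 and CH4; liquid water), all at the reference temperature
#' 298.15 K. Temperature extrapolation of the standard Gibbs energy uses the
#' van't Hoff / Gibbs-Helmholtz relation with constant reaction enthalpy,
#' which is adequate over the 300-350 K range the reactor explores.
#'
#' @param constants Named numeric vector of formation properties, as returned
#'   by [read_key_value()] on the shipped `thermo_constants.tsv`. Defaults to
#'   the shipped table.
#' @return An object of class `reaction_thermo` with elements
#'   `stoichiometry` (named integer vector), `standard_gibbs_energy` (J/mol),
#'   `standard_enthalpy` (J/mol) and `reference_temperature` (K).
#' @examples
#' th <- methanogenesis_thermo()
#' th$standard_gibbs_energy  # about -194 kJ/mol: strongly exergonic
#' @export
methanogenesis_thermo <- function(constants = NULL) {
  if (is.null(constants)) {
    path <- system.file("extdata", "thermo_constants.tsv",
                        package = "ventmethane", mustWork = TRUE)
    constants <- read_key_value(path)
  }
  need <- c("gibbs_formation_CO2_aq", "gibbs_formation_H2_aq",
            "gibbs_formation_CH4_aq", "gibbs_formation_H2O_l",
            "enthalpy_formation_CO2_aq", "enthalpy_formation_H2_aq",
            "enthalpy_formation_CH4_aq", "enthalpy_formation_H2O_l",
            "reference_temperature_K")
  missing <- setdiff(need, names(constants))
  if (length(missing)) stop("constants table lacks: ", paste(missing, collapse = ", "))

  stoich <- c(CO2 = -1L, H2 = -4L, CH4 = 1L, H2O = 2L)
  dG0 <- sum(stoich * constants[c("gibbs_formation_CO2_aq",
                                  "gibbs_formation_H2_aq",
                                  "gibbs_formation_CH4_aq",
                                  "gibbs_formation_H2O_l")])
  dH0 <- sum(stoich * constants[c("enthalpy_formation_CO2_aq",
                                  "enthalpy_formation_H2_aq",
                                  "enthalpy_formation_CH4_aq",
                                  "enthalpy_formation_H2O_l")])
  if (dG0 >= 0) stop("assembled standard Gibbs energy is non-negative; ",
                     "the catabolic reaction must be exergonic at standard state")
  structure(
    list(stoichiometry = stoich,
         standard_gibbs_energy = unname(dG0),
         standard_enthalpy = unname(dH0),
         reference_temperature = unname(constants["reference_temperature_K"])),
    class = "reaction_thermo")
}

#' @export
print.reaction_thermo <- function(x, ...) {
  cat("Reaction: CO2 + 4 H2 -> CH4 + 2 H2O\n")
  cat(sprintf("  dG0(%g K) = %.2f kJ/mol\n", x$reference_temperature,
              x$standard_gibbs_energy / 1e3))
  cat(sprintf("  dH0       = %.2f kJ/mol\n", x$standard_enthalpy / 1e3))
  invisible(x)
}

#' Reaction quotient of methanogenesis
#'
#' Q = \[CH4\] / (\[CO2\] \[H2\]^4), with activities taken as molar
#' concentrations (ideal dilute solution) and water activity fixed at 1.
#'
#' @param conc_co2,conc_h2,conc_ch4 Concentrations in mol/L; must be >= 0.
#' @return Dimensionless reaction quotient. Zero CH4 gives `Q = 0`.
#' @examples
#' reaction_quotient(1e-3, 1e-2, 2e-3)  # 2e8 at reactor start conditions
#' @export
reaction_quotient <- function(conc_co2, conc_h2, conc_ch4) {
  if (any(c(conc_co2, conc_h2, conc_ch4) < 0) ||
      anyNA(c(conc_co2, conc_h2, conc_ch4))) {
    stop("concentrations must be non-negative and finite")
  }
  denom <- conc_co2 * conc_h2^4
  if (denom == 0 && conc_ch4 == 0) {
    stop("indeterminate reaction quotient: numerator and denominator both zero")
  }
  conc_ch4 / denom
}

#' Standard Gibbs energy of reaction at temperature T
#'
#' Gibbs-Helmholtz extrapolation with constant reaction enthalpy:
#' dG0(T) = dH0 + (T / Tref) (dG0(Tref) - dH0). Exactly reproduces the
#' embedded dG0 at the reference temperature.
#'
#' @param temperature Temperature in K (> 0).
#' @param thermo A [methanogenesis_thermo()] object.
#' @return Standard reaction Gibbs energy in J/mol.
#' @export
standard_gibbs_at <- function(temperature, thermo = methanogenesis_thermo()) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  thermo$standard_enthalpy +
    (temperature / thermo$reference_temperature) *
    (thermo$standard_gibbs_energy - thermo$standard_enthalpy)
}

#' Gibbs energy of reaction at given conditions
#'
#' dG = dG0(T) + R T ln Q. This is the per-mole energy yield that pays the
#' methanogens' maintenance and growth costs in the reactor; metabolism is
#' thermodynamically gated off when dG >= 0.
#'
#' @param temperature Temperature in K (> 0).
#' @param quotient Reaction quotient Q >= 0. `Q = 0` returns `-Inf` (the
#'   documented sentinel for a product-free mixture).
#' @param thermo A [methanogenesis_thermo()] object.
#' @return Gibbs energy of reaction in J/mol.
#' @examples
#' th <- methanogenesis_thermo()
#' gibbs_energy(300, reaction_quotient(1e-3, 1e-2, 2e-3), th) # < 0: favourable
#' @export
gibbs_energy <- function(temperature, quotient, thermo = methanogenesis_thermo()) {
  if (any(temperature <= 0) || anyNA(temperature)) stop("temperature must be positive")
  if (any(quotient < 0) || anyNA(quotient)) stop("reaction quotient must be >= 0")
  standard_gibbs_at(temperature, thermo) +
    .R_GAS * temperature * log(quotient)
}
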