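Package: ventmethane
Title: Methanogen Bioenergetics in Hydrothermal Vents and the Detectability
    of the Resulting Atmospheric Methane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up toy-model pipeline linking the bioenergetics of
    hydrogenotrophic methanogens in low-temperature hydrothermal-vent
    bioreactors to global atmospheric methane mixing ratios on an
    Archean-Earth-like exoplanet, and onwards to the detectability of that
    methane with proposed direct-imaging observatories (LUVOIR A/B, HabEx
    with and without a starshade, and 6 m rescaled variants). Provides a
    deterministic time-stepped reactor simulator with maintenance-energy
    gating and limit-cycle population dynamics, a linear flux-to-mixing-ratio
    atmospheric box model with vent-coverage scaling, a Gaussian-band
    reflected-light contrast model with a photon-counting instrument noise
    budget, and seeded synthetic-data generators that make the whole chain
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
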