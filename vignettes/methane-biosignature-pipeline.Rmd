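---
title: "From vent methanogens to a detectable methane biosignature: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vent methanogens to a detectable methane biosignature: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmethane)
```

`ventmethane` chains three toy models end to end: a deterministic bioreactor
of hydrogenotrophic methanogens living around low-temperature hydrothermal
vents on an Archean-Earth-like ocean world; a linear box model scaling the
reactor's methane output to a global atmospheric mixing ratio via the
fraction of ocean floor covered by vents; and a photon-counting noise model
of proposed direct-imaging observatories (LUVOIR A/B, HabEx with and without
a starshade) that turns a methane mixing ratio into a 5-sigma detection
time. Every stage is deliberately first-order: the aim is a transparent,
fully testable account of how microbial ecology propagates to an observable,
not fidelity to any one radiative-transfer or metabolic code.

This vignette is the package's methods record: the model equations and
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the synthetic fixtures do and do not establish about real
systems.

## 1. Bioenergetics

The organisms run the catabolic reaction

$$\mathrm{CO_2} + 4\,\mathrm{H_2} \rightarrow \mathrm{CH_4} + 2\,\mathrm{H_2O},$$

with energy yield per mole
$\Delta G = \Delta G^\circ(T) + R T \ln Q$, where
$Q = [\mathrm{CH_4}] / ([\mathrm{CO_2}][\mathrm{H_2}]^4)$ uses molar
concentrations as activities (ideal dilute solution) and water activity 1.
Standard-state formation properties for aqueous CO~2~, H~2~, CH~4~ and
liquid water are taken from the Amend & Shock (2001) compilation and shipped
as a plain-text table (`inst/extdata/thermo_constants.tsv`); the assembled
reaction values are $\Delta G^\circ(298.15\,\mathrm{K}) = -193.6$ kJ/mol and
$\Delta H^\circ = -229.0$ kJ/mol, and the test suite re-derives them by an
independent hand summation. Other compilations differ by a few kJ/mol; no
attempt is made to tune the choice, and at the reactor's inflow-limited
operating points the production rates are insensitive to it.

Temperature dependence uses the Gibbs–Helmholtz (van't Hoff) extrapolation
with constant reaction enthalpy,
$\Delta G^\circ(T) = \Delta H^\circ + (T/T_{\mathrm{ref}})(\Delta G^\circ(T_{\mathrm{ref}}) - \Delta H^\circ)$,
which is adequate over the 300–350 K range explored and avoids
heat-capacity data. The 250 bar ambient pressure is carried as metadata
only: no pressure correction is applied to $\Delta G$, because the regimes
that matter downstream are substrate-inflow-limited, not
thermodynamics-limited. Ionic-strength corrections, carbonate speciation and
pressure-explicit thermodynamics are out of scope.

## 2. The vent bioreactor

One reactor is 1 L of vent fluid at 300 K holding dissolved CO~2~
(1 mmol/L), H~2~ (10 mmol/L) and CH~4~ (2 mmol/L) at start, stepped forward
at $\Delta t = 1000$ s for $10^8$ s with constant substrate inflows.
Methane accumulates for the whole run; there is no outflow. Each step
applies, in fixed order:

1. inflow: concentrations gain `inflow * dt`;
2. thermodynamic gate: $\Delta G$ at current concentrations; if
   $\Delta G \ge 0$ metabolism is skipped;
3. demand: per-cell rate $R = \min(k[\mathrm{CO_2}],\ r_{\max})$ and total
   turnover $x = \min(R N \Delta t,\ [\mathrm{CO_2}],\ [\mathrm{H_2}]/4)$
   (limiting-reagent cap), with $N$ the whole living population — stasis
   cells are reconsidered every step;
4. concentration update with 4:1 H~2~:CH~4~ stoichiometry;
5. energy accounting: $E = x V |\Delta G|$ supports
   $\lfloor E / (P_m \Delta t) \rfloor$ cells at maintenance power
   $P_m = 5.32\times10^{-14}$ J/s; cells beyond that rest in stasis
   (consuming nothing, still ageing); surplus energy accrues to a growth
   pool and converts to $\lfloor \mathrm{pool} / E_{\mathrm{syn}} \rfloor$
   new cells in a new cohort;
6. cohorts whose age has reached the $10^6$ s life span are removed — except
   the 500-cell founder cohort, which is immortal so the community can
   always reboot after a crash.

The rate law in step 3 is the simplest form consistent with the two
published kinetic constants (a first-order constant
$k = 2.88\times10^{-5}$ /s and a per-cell ceiling
$r_{\max} = 1.06\times10^{-18}$ mol/L/s); with these values the ceiling
binds except at CO~2~ below $\sim 4\times10^{-14}$ mol/L. The cell synthesis
cost $E_{\mathrm{syn}}$ is a free parameter (default $10^{-11}$ J): no
observation constrains it, and in the inflow-limited regime mean production
changes by well under 5% when it moves tenfold, because total biomass simply
adjusts to the available energy — the suite asserts exactly that, and the
same insensitivity holds for temperature between 300 and 350 K.

Numerics: forward-Euler stepping; concentrations floored at zero after the
update (the limiting-reagent cap makes the floor a pure rounding guard);
CH~4~ floored at $10^{-30}$ mol/L inside the gate so a product-free start
cannot propagate an infinite energy yield; no randomness anywhere.
`run_reactor()` keeps the population in an $O(1)$-per-step ring-buffer death
queue, while `reactor_step()` exposes the same rules over explicit cohort
vectors; a test pins the two to each other and a third, independently
hand-coded brute-force stepper.

### Limit cycles and averaging

In substrate-starved regimes the community booms on the accumulated stock,
outpaces the inflow, crashes back to the founder cohort when the boom
generation's life span elapses, and reboots once inflow has replenished the
reactor — a deterministic boom–crash limit cycle spanning many orders of
magnitude in population. Production is therefore reported as a windowed
mean, `mean_production()`: cumulative CH~4~ over the final $10^7$ s divided
by the window (overridable). Cycle counts are diagnosed as upward crossings
of the log-scale population midrange.

### The inflow grid and a deliberate caveat

`run_grid()` sweeps mean production over a log-spaced 21 × 21 factorial grid
of CO~2~ and H~2~ inflows from $10^{-12}$ to $10^{-6}$ mol/L/s (441
simulations; failures are flagged per cell, never fatal). Production rises
along the H~2~ axis monotonically. Along the CO~2~ axis it does **not**
always: the reactor starts with a large H~2~ stock, and a faster CO~2~
supply burns that stock *before* the final averaging window, so a cell that
was CO~2~-limited (production equal to CO~2~ inflow, stock subsidising the
hydrogen) can drop to the much lower H~2~-inflow-limited rate when CO~2~
inflow increases. This is a real property of a no-outflow reactor with
finite initial stocks and end-of-run averaging, not a numerical artefact;
the acceptance suite documents it as a failing monotonicity expectation
along the CO~2~ axis, with the H~2~ axis asserted green.

On the full default grid the extremes bracket the expected range (minimum at
or below $10^{-11}$, maximum of a few $10^{-7}$ mol/L/s at the top corner,
where the 4:1 hydrogen stoichiometry caps long-run production near
`inflow_h2 / 4`). Exact extreme values depend on internals of other
simulators and are deliberately not targeted.

## 3. From reactor to atmosphere

The per-litre production rate $p$ scales to a global biotic flux through the
vent fluid volume implied by a fractional ocean-floor coverage $c$:
$V = c \cdot A_{\mathrm{ocean}} \cdot h$ with mean vent height
$h = 10$ m, and

$$F_{\mathrm{bio}} = p V \cdot \frac{3.1536\times10^7\ \mathrm{s/yr}}{10^{12}}\ \ \mathrm{Tmol/yr},
\qquad F = \eta F_{\mathrm{bio}} + F_{\mathrm{abiotic}},$$

with outgassing fraction $\eta = 1$ (best case) or $0.2$ (conservative —
most oceanic methane is oxidised before it escapes) and a flat
$F_{\mathrm{abiotic}} = 10$ Tmol/yr covering all non-biological sources. The
atmospheric mixing ratio follows the linear hydrogen-balance relation with a
one-third correction for unmodelled sinks,

$$f_{\mathrm{CH_4}} = \frac{F}{3 \times 6680\ \mathrm{Tmol/yr}},$$

so 10, 50 and 200 Tmol/yr map to 0.05%, 0.25% and 1% — the
abiotic/biogenic threshold, "likely biogenic" and "very likely biogenic"
levels used by `classify_mixing_ratio()` (half-open bins). The chain is
linear, so `coverage_for_mixing()` and `rate_for_mixing()` invert it in
closed form; impossible demands are flagged (`infeasible` when more than
full coverage would be needed) rather than clipped. A 365-day year is used;
the difference from a Julian year is below 0.2%, far inside the rounding the
chain carries.

Two ocean-area constants circulate for the same planet: $3.62\times10^7$
km² (the value the headline coverage numbers are arithmetically consistent
with, and the default) and $3.62\times10^8$ km² (the value in the underlying
hypsometry source, and the one consistent with a modern-Earth vent census of
~8000 vents × 100 m² ≈ $2.2\times10^{-7}$% coverage). They differ by ten and
cannot both be right; `vent_coverage_model()` exposes both as named presets
and takes no side. For the same reason `vent_census()` takes surveyed vent
density and ridge length as explicit inputs. Atmospheric lifetime, ocean
transport beyond the single $\eta$ factor, and climate feedbacks are out of
scope.

## 4. Detectability

### Scene and spectra

The planet is an Earth twin (1 R⊕, 1 AU, geometric albedo 0.3) around a
Sun-like star (5772 K blackbody), observed at quadrature from 5–20 pc for
100 h. The atmosphere is anoxic and Archean-like — 94% N~2~, 5% CO~2~, 1%
H~2~O, 10 ppm CO, 0.1% CH~4~ before normalization — at 1 atm and a flat
210 K, with no vertical structure, photochemistry, clouds or haze (all
deliberately excluded; hydrocarbon haze in particular would matter above
roughly half a percent of methane and is left to more capable models).
`compose_atmosphere()` sets the methane fraction and rescales the other
gases so their mutual ratios are preserved, renormalizing to exact unit sum.

Planet-to-star contrast is a two-pass Beer–Lambert slab over a grey Lambert
reflector:

$$C(\lambda) = A_g\,\Phi\,(R_p/a)^2\,
\exp\!\big(-2 N_{\mathrm{col}} \textstyle\sum_g f_g \sigma_g(\lambda)\big),$$

with quadrature phase factor $\Phi = 1/\pi$ and hydrostatic column
$N_{\mathrm{col}} = P N_A / (\bar m g) \approx 2.17\times10^{29}$ m⁻² at
1 atm. Cross sections come from the package's Gaussian band library, not a
line database: CH~4~ carries its standard visible/near-infrared band ladder
(0.62–1.67 µm) with peak cross sections of order $10^{-29}$–$10^{-27}$ m²
chosen to follow the familiar low-resolution progression (strengthening
towards the near infrared), and CO~2~/H~2~O carry their usual bands placed
so no centre falls within one band width of a methane centre. Band depths
are therefore representative, not database-accurate: the package asserts
orderings and scalings (instrument ranking, aperture scaling, distance and
concentration trends), never absolute exposure times, which would require a
full radiative-transfer pipeline.

### Noise model

Table-driven instrument descriptions (`luvoir_a()`, `luvoir_b()`,
`habex_ss()`, `habex_no_ss()`) carry aperture, per-channel wavelength range
and resolving power, detector read and dark noise, optical and
coronagraph/starshade throughputs, raw contrast, inner working angle and an
exozodi level. Only the visible and near-infrared channels are modelled —
no methane bands exist below 0.45 µm, so ultraviolet channels would
contribute zero signal. Bins tile each channel multiplicatively at width
$\lambda/R$. Per bin, over exposure $t$ with collecting area $A$ and
throughput $T$:

* planet counts $C_p = C(\lambda)\, r_\star A T t$, with $r_\star$ the
  blackbody stellar photon rate;
* starlight leak $C_\ell$ at the instrument's raw contrast through the same
  chain;
* zodiacal background $C_z = z \cdot \zeta_{\mathrm{fid}} A t$ with
  exozodi level $z = 4.5$ and a fiducial rate
  $\zeta_{\mathrm{fid}} = 5\times10^{-9}$ photons s⁻¹ m⁻² per bin — crude by
  design, sized to be a minor but non-zero term at these apertures;
* dark current $d\,t$ and read noise $\rho^2 n_{\mathrm{frames}}$ with
  1000 s frames.

Noise is $N_i = \sqrt{C_p + C_\ell + C_z + d t + \rho^2 n_{\mathrm{frames}}}$.
The detection statistic compares a candidate methane atmosphere with a
baseline one:

$$S/N = \sqrt{\sum_i \big((S_{i,\mathrm{new}} - S_{i,\mathrm{base}})/N_i\big)^2},
\qquad t_{5\sigma} = 100\,\mathrm{h} \times (5 / (S/N))^2 .$$

$N_i$ is taken from the baseline observation, a choice the source material
leaves open; it makes the statistic exactly zero for identical inputs. The
baseline methane level defaults to 0.05% — the highest level not requiring
a biological source — with 0.1% (the plain template atmosphere) available
by argument; the two conventions circulate side by side upstream and the
package surfaces both rather than resolving them.

### Inner working angles

`iwa_check()` is the conservative channel diagnostic: $\lambda/D$ IWAs are
evaluated at the channel's red edge, fixed-mas starshade IWAs as given
(HabEx SS NIR, 104 mas, fails a 100 mas separation at 10 pc by 4%).
`observe()` deliberately does **not** hard-mask on that basis by default:
under the `"flag"` policy it integrates every bin and flags feasibility as
"the planet is outside the IWA somewhere in at least one channel", because
the published instrument comparisons integrate the full band at marginal
separations, and because red-edge masking would blind an 8 m coronagraph to
a 1 AU planet beyond ~12 pc, contradicting the comparisons the model exists
to reproduce. The `"mask"` policy is available for users who want the hard
cut (per-bin for $\lambda/D$ instruments, per-channel for fixed-mas ones).
`rescale_mirror()` changes only the aperture — throughputs, noise and
contrast are retained, $\lambda/D$ IWAs re-evaluate, mas IWAs stay — which
is exactly the rough what-if the 6 m comparisons intend, not an instrument
redesign.

Under this model, at 10 pc the detection-time ranking is LUVOIR A < LUVOIR B
< HabEx SS < HabEx no SS; 1% methane always beats 0.25%; times grow with
distance; and at an equal 6 m aperture the starshade HabEx beats LUVOIR B
because every throughput term is larger at equal contrast. In the shot-noise
limit $S/N \propto D$, so $t_{5\sigma} \propto D^{-2}$ — all asserted by the
suite.

## 5. Synthetic data

The generators exist so the whole chain is testable offline, with explicit
seeds and no hidden global randomness:

* `default_band_library()` — the deterministic Gaussian band set above;
  serializable to the same plain-text key-value format as the thermodynamic
  constants.
* `mock_observation()` — Poisson-resampled signal counts at an explicit
  seed (the global RNG stream is left untouched), for validating the S/N
  statistic against sampling noise.
* `sawtooth_series()` — a discrete sawtooth limit-cycle stand-in whose
  sampled mean equals the requested mean exactly, used to pin
  `mean_production()` to closed-form values at $10^{-6}$ relative.

What passing these tests shows: the estimator recovers known means, the
noise calculus is internally consistent, and the pipeline's orderings follow
from its stated assumptions. What they do not show: that real vent fields,
real atmospheres or real instruments behave like the toy models — the band
shapes are Gaussians, the star a blackbody, the reactor a single well-mixed
litre.

## 6. Orchestration and reproducibility

`pipeline_config()` holds every study constant as a default (the shipped,
commented `inst/extdata/default_config.yaml` is the authoritative record;
YAML stands in for an ini-style format because it is the structured
plain-text format available to the package's dependencies). Unknown keys are
rejected. The three experiment runners write deterministic CSV — scientific
notation at nine significant digits, a config-hash comment instead of
timestamps — so identical configurations reproduce byte-identical files;
logs go to standard error. The runners are ordinary R functions; together
with `scripts/acceptance.R` they are the package's command surface.

Problem sizes: the full 441-cell grid at $10^5$ steps per simulation runs in
a few minutes and is the user-facing default. The test suite exercises the
same code on 3×3 and 5×5 grids (shortened runs for behavioural tests;
full-length runs for the corner cells and the 5×5 monotonicity sweep, which
is where the grid extremes live), keeping the whole suite under a minute
without changing any model constant.

## 7. Known limitations

* No CHNOPS nutrient bookkeeping: biomass elements are assumed surplus, so
  every computed coverage requirement is a lower bound.
* No methane outflow from the reactor during the run; production rates are
  time-averages over an accumulating, increasingly product-inhibited system.
* The flux-to-mixing-ratio relation is a single linear anchor; no
  photochemistry, no altitude dependence, no lifetime dynamics.
* Absolute detection times are not comparable to full radiative-transfer
  pipelines; only orderings and scalings are meaningful.
* The ocean-area inconsistency documented in section 3 propagates a factor
  ten into any absolute coverage statement; both presets are provided.
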