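# Default pipeline configuration: the authoritative record of every study
# constant. Any file passed to read_pipeline_config() may override a subset
# of these keys; unknown keys are rejected.

reactor:
  temperature: 300            # K; moderate mixing zone around a vent
  pressure: 2.5e+7             # Pa; deep-ocean ambient, metadata only
  volume: 1                   # L
  conc_co2: 1.0e-3            # mol/L initial dissolved CO2
  conc_h2: 1.0e-2             # mol/L initial dissolved H2 (serpentinization)
  conc_ch4: 2.0e-3            # mol/L initial dissolved CH4
  dt: 1000                    # s time step
  t_end: 1.0e+8                # s total simulated time
  averaging_window: 1.0e+7     # s final window for mean production
  maintenance_power: 5.32e-14 # J/s per cell (anaerobe estimate)
  max_metabolic_rate: 1.06e-18 # mol/L/s per cell ceiling
  rate_constant: 2.88e-5      # 1/s first-order constant in CO2
  life_span: 1.0e+6            # s; cohorts older than this are removed
  synthesis_energy: 1.0e-11   # J per new cell (free parameter)
  founder_population: 500     # immortal founder cohort

grid:
  n_inflow: 21                # 21 x 21 = 441 simulations
  inflow_min: 1.0e-12         # mol/L/s
  inflow_max: 1.0e-6          # mol/L/s

atmosphere:
  eta: [1.0, 0.2]             # outgassing fraction: best case / conservative
  ocean_area_preset: headline # "headline" = 3.62e7 km2; "census" = 3.62e8 km2
  vent_height: 10             # m mean vent height
  abiotic_flux: 10            # Tmol/yr non-biological methane floor
  thresholds: [5.0e-4, 2.5e-3, 1.0e-2]  # mixing-ratio classification edges
  coverage_min: 1.0e-10
  coverage_max: 1
  n_coverage: 41
  rate_min: 1.0e-17           # mol/L/s surface axis
  rate_max: 1.0e-6
  n_rate: 45

detectability:
  instruments: ["LUVOIR A", "LUVOIR B", "HabEx SS", "HabEx no SS"]
  distances_pc: [5, 10, 15, 20]
  ch4_fractions: [2.5e-3, 1.0e-2]   # candidate methane mixing ratios
  baseline_ch4: 5.0e-4        # reference atmosphere for the difference S/N
  exposure_time_h: 100
  include_6m: false           # add 6 m rescaled HabEx SS / LUVOIR B rows
  iwa_policy: flag            # "flag" records IWA status; "mask" excludes bins

output_dir: "."
log_level: info
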