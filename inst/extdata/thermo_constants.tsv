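# Standard-state thermodynamic formation properties at 298.15 K, 1 bar.
# Source compilation: Amend & Shock (2001), "Energetics of overall metabolic
# reactions of thermophilic and hyperthermophilic Archaea and Bacteria",
# FEMS Microbiology Reviews 25, Tables of standard molal properties.
# Aqueous species use the ideal dilute (molal) standard state; H2O is liquid.
# Columns: key <TAB> value (J/mol unless noted)
gibbs_formation_CO2_aq	-385974
gibbs_formation_H2_aq	17723
gibbs_formation_CH4_aq	-34354
gibbs_formation_H2O_l	-237183
enthalpy_formation_CO2_aq	-413798
enthalpy_formation_H2_aq	-4200
enthalpy_formation_CH4_aq	-87906
enthalpy_formation_H2O_l	-285830
reference_temperature_K	298.15
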