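{
  "faraday_kcal_per_mol_V": 23.0605,
  "gas_constant_kcal_per_mol_K": 0.0019872,
  "boltzmann_over_planck_per_s_K": 20836619123.3276,
  "hc_eV_nm": 1239.84,
  "proton_solvation_kcal_per_mol": -265.9,
  "she_absolute_V": 4.43,
  "default_temperature_titration_K": 300,
  "default_temperature_kinetics_K": 298.15,
  "coulomb_constant_kcal_A_per_mol_e2": 332.0636
}
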