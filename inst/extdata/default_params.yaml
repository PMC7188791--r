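kinetic:
  vmax_O2: 7.2
  K_O2: 0.5
  vmax_NAR: 40.0
  K_NO3: 50.0
  vmax_NIR: 100.0
  K_NO2: 20.0
  vmax_NOR: 300.0
  K_NO: 0.15
  vmax_N2OR: 100.0
  K_N2O: 0.1
  KI_O2_NAR: 1.0
  KI_O2_NIR: 0.05
  KI_O2_NOR: 0.05
  KI_O2_N2OR: 0.2
  K_NO_tox: 0.9
  k_nit: 0.11
  e_supply_N: 5.0
  yield: 3.0e+07
  kLa_O2: 50.0
  kLa_NO: 50.0
  kLa_N2O: 50.0
regulatory:
  K_hypoxia: 3.0
  hill_hypoxia: 2.0
  K_NO_sensor: 0.02
  nirK_nitrite_induction: no
  K_NO2_sensor: 100.0
  alpha_basal: 0.02
  alpha_max:
    narG: 20.0
    nirK: 20.0
    norZ: 20.0
    nosZ: 20.0
  delta_m: 2.0
  k_transl:
    narG: 0.9
    nirK: 2.2
    norZ: 5.5
    nosZ: 1.9
  k_degE:
    NAR: 0.01
    NIR: 0.05
    NOR: 0.025
    N2OR: 0.025
  K_syn: 0.2
  microoxic_gate: yes
  rna_ng_per_cell: 0.0001
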