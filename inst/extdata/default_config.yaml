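constants:
  dHf_kcal_mol: 1.436
  T_R_K: 273.15
  R_um3atm: 8.20574e+13
  R_kcal: 0.0019872
  vw_um3_mol: 1.802e+13
cell:
  V0_um3: 1774.2238801
  vb_frac: 0.25
  Lpg_um_min_atm: 0.1166
  ELp_kcal_mol: 11.9236
  phi_diss: 2.0
  vs_um3_mol: 1.66e+13
  T0_C: -0.5
free_volume:
  eta_w0_mPas: 0.0333
  Vhat_w_cm3_g: 0.91
  K11_over_lambda_cm3_gK: 0.001945
  K21_K: -19.73
  T_gw_K: 136.0
nucleation:
  scn:
    Omega0_per_m2_s: 5.0e+08
    kappa0_K5: 4.3e+09
    vf_frac: 0.45
  vcn:
    Omega0_per_m3_s: 5.0e+15
    kappa0_K5: 5.0e+10
    vf_frac: 0.36
protocol:
  rates_C_per_min:
  - 45.0
  - 60.0
  - 75.0
  - 100.0
  T_start_C: -0.5
  T_end_C: -50.0
  grid_dK: 0.05
fitting:
  n_starts_volume: 4.0
  n_starts_pif: 20.0
  seed: 1.0
  weighting: none
io:
  delimiter: ','
  digits: 6.0
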