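variant: model3
kinetic:
  nu_p: 0.02
  nu_n: 0.6
  rho_c: 0.6
  rho_u: 8.2
  rho_d: 0.6
  gamma: 0.16
mech:
  R: 5.0
  sigma: 0.3333333
  E_mod: 1000.0
  eta: 10.0
  noise_amp: 0.0
  pressure_threshold: 13000.0
cycle:
  t_G1: 420.0
  t_M: 120.0
  rest_min: 480.0
  rest_max: 1080.0
duration: 10080.0
dt: 0.01
seed: 1
snapshot_interval: 1440.0
forced_times:
- 4320.0
- 10080.0
contact_inhibition: yes
cycle_enabled: yes
collapse_check: yes
collapse_frac: 0.2
displacement_cap: 0.05
max_substeps: 50
min_distance_frac: 0.1
drain_tol: 1.0e-06
scenario: single_cell_colony
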