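shape:
  endo_long_radius: 30.0
  endo_short_radius: 15.0
  wall_thickness_apex: 4.0
  wall_thickness_equator: 7.0
  truncation_fraction: 0.75
  n_circumferential: 16
  n_transmural: 3
  n_longitudinal: 6
material:
  a: 1.05
  b: 7.542
  a_f: 3.465
  b_f: 14.472
  a_s: 0.481
  b_s: 12.548
  a_fs: 0.283
  b_fs: 3.088
  kappa: 1000.0
  macaulay: yes
boundary:
  p_ed: 1.33322
  penalty_slope: 2.0
solver:
  n_increments: 12000
  settle_increments: 4000
  damping: 90.0
  mass_safety: 4.0
  checkpoint_fractions:
  - 0.2
  - 0.4
  - 0.6
  - 0.8
  - 1.0
  ke_check_interval: 50
  contact_interval: 10
  ke_tolerance: 0.05
mask:
  spacing: 2.0
  threshold: 0.25
  closing_diameter: 6.0
bo:
  beta: 10.0
  beta_scale: sqrt
  n_iterations: 10.0
  init_params:
  - - 0.0
    - 1.0
  - - 1.0
    - 0.0
  - - 1.0
    - 1.0
  acquisition_grid: 101.0
  noise_floor: 0.0001
  seed: 1.0
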