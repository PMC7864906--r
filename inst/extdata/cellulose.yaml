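name: cellulose
reference_mass: 100.0
grid:
  p_min: 0.0
  p_max: 2.0
  dp: 0.01
  uptake_frac: 0.2
solver:
  dt: 0.1
  t_end: 365.0
  output_every: 1.0
classes:
- name: plant_sugar
  accessible: 95.0
  inaccessible: 0.0
  input_accessible: 0.0
  input_inaccessible: 0.0
  to_accessible: 0.0
  to_inaccessible: 0.0
  center_frac: 0.25
  sd_frac: 0.05
communities:
- name: plant_decomposer
  biomass: 5.0
  e0: 0.4
  m0: 0.02
  u0:
    plant_sugar: 5.0
  signature: []
enzymes:
- name: cellulolysis
  target: plant_sugar
  tau0: 1.8
  alpha: 5.0
  producers:
    plant_decomposer: 1.0
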