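name: succession_cheating
reference_mass: 100.0
grid:
  p_min: 0.0
  p_max: 2.0
  dp: 0.01
  uptake_frac: 0.2
solver:
  dt: 0.1
  t_end: 1500.0
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
- name: lignin
  accessible: 30.0
  inaccessible: 0.0
  input_accessible: 0.0
  input_inaccessible: 0.0
  to_accessible: 0.0
  to_inaccessible: 0.0
  center_frac: 0.25
  sd_frac: 0.05
- name: mic_sugar
  accessible: 0.0
  inaccessible: 0.0
  input_accessible: 0.0
  input_inaccessible: 0.0
  to_accessible: 0.0
  to_inaccessible: 0.0
  center_frac: 0.25
  sd_frac: 0.05
- name: lipid
  accessible: 0.0
  inaccessible: 0.0
  input_accessible: 0.0
  input_inaccessible: 0.0
  to_accessible: 0.0
  to_inaccessible: 0.0
  center_frac: 0.25
  sd_frac: 0.05
- name: protein
  accessible: 0.0
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
    lignin: 5.0
    mic_sugar: 3.0
    lipid: 3.0
    protein: 3.0
  signature:
    mic_sugar: 0.5
    lipid: 0.3
    protein: 0.2
- name: mic_decomposer
  biomass: 5.0
  e0: 0.5
  m0: 0.01
  u0:
    plant_sugar: 3.0
    lignin: 3.0
    mic_sugar: 5.0
    lipid: 5.0
    protein: 5.0
  signature:
    mic_sugar: 0.5
    lipid: 0.3
    protein: 0.2
enzymes:
- name: cellulolysis
  target: plant_sugar
  tau0: 1.8
  alpha: 5.0
  producers:
    plant_decomposer: 1.0
- name: lignolysis
  target: lignin
  tau0: 1.0
  alpha: 7.0
  producers:
    plant_decomposer: 1.0
- name: lipidolysis
  target: lipid
  tau0: 0.8
  alpha: 1.5
  producers:
    mic_decomposer: 1.0
- name: proteolysis
  target: protein
  tau0: 1.8
  alpha: 5.5
  producers:
    mic_decomposer: 1.0
- name: mic_sugar_lysis
  target: mic_sugar
  tau0: 1.8
  alpha: 5.0
  producers:
    mic_decomposer: 1.0
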