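# Minimal three-layer mat scenario for demonstrations: oxygenic
# photosynthesis in the middle layer, respiration above and below,
# chlorophyll a and phycocyanin bands, thin salt crust.
layer_boundaries: [0, 1.5, 3, 5]
porosity: 0.3
seed: 1
rates:
  O2_light: [-8.0e-5, 1.6e-4, -6.0e-5]
diffusivity:
  O2_light: 1.5e-9
boundary_conditions:
  O2_light:
    top: {type: concentration, value: 0.25}
    bottom: {type: concentration, value: 0.0}
pigment_bands:
  - {name: chl_a, center_wavelength: 674, bandwidth_sigma: 8,
     peak_attenuation: 1.0, depth_center: 1.8, depth_sigma: 0.5}
  - {name: phycocyanin, center_wavelength: 624, bandwidth_sigma: 10,
     peak_attenuation: 0.7, depth_center: 2.0, depth_sigma: 0.5}
matrix_attenuation: [1.3, 1.3, 1.3]
salt: {thickness_mm: 1.2, attenuation: 0.008}
srr_truth:
  edges_mm: [0, 3.2, 11.2, 19.2, 27.2, 30]
  rates: [5.0e-7, 4.4e-6, 2.6e-6, 1.4e-6, 9.0e-7]
tracer:
  sulfate_mol_m3: 300
  porosity: 0.35
  incubation_time_s: 23400
  total_activity_kBq: 200
noise_sd:
  concentration: 0.001
  irradiance: 0.002
  activity_sdlog: 0.1
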