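out_dir: pipeline_out
rng_seed: 1.0
extent_km: 120.0
res_terrain_m: 250.0
res_ndvi_m: 500.0
n_roads: 16.0
n_residents: 6.0
n_dispersers: 4.0
n_exploratory: 2.0
n_migrants: 4.0
true_betas:
  ruggedness: -0.1
  ruggedness_sq: -0.3
  ndvi: 0.8
  dist_roads: 0.1
  canopy: 0.2
  canopy_sq: -0.25
window_days: 26.0
bin_width_m_min: 0.5
n_random: 10.0
k_folds: 5.0
n_perm: 200.0
n_crw_paths: 10.0
trim_start_hr: 48.0
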