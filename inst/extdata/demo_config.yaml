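# Demo configuration: small synthetic fibrotic phantom, full pipeline.
seed: 1
output_dir: fibroct_demo_out
phantom:
  shape_um: [150, 150, 100]
  voxel_size_um: 2.5
  target_coll_fraction: 0.30
  bundle_radius_um: [10, 2]
  orientation_axis: [0, 0, 1]
  orientation_kappa: 5
  muscle_grey: [90, 12]
  collagen_grey: [140, 14]
  bright_spot_rate: 50
  noise_sd: 0
analysis:
  subvolume_size_um: [75, 75, 50]
  n_threshold_slices: 12
  mdd_reference_P: 0.005
  da_convention: paper
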