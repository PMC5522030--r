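# Demonstration configuration for the full synthetic experiment.
# Reduced grid so the demo runs in seconds; drop the phantom block to use
# the full-scale defaults (32^3 grid, b = 1200 s/mm^2, 27 directions + b0,
# SNR 20).
seed: 7
phantom:
  grid_shape: [22, 22, 22]
  core_radius: 3
  shell_outer_radius: 7
  capsule_thickness_mm: 2
  snr: 20
tracking:
  angle_threshold_deg: 35
  step_size_mm: 1.0
  max_length_mm: 30
  seeds_per_voxel: 2
bands:
  core: [1.0, 6.0]
  shell: [8.0, 30.0]
cohort:
  n_subjects: 62
  censoring_fraction: 0.177
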