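# Demo configuration for run_pipeline(): a small, fast, fully seeded run.
# Fields are 64 um (256 px at 0.25 um/px), so the cells-per-field confluency
# cutoff is scaled down accordingly (cutoffs are defined per field of view).
design:
  method: constant_density
  cell_type: HUVEC
  time_points_hr: [24, 96]
  slides_per_condition: 5
  n_experiments: 1
  seed: 101
  wpb_per_cell_curve:
    type: constant
    value: 8
  scene:
    field_width_px: 256
    field_height_px: 256
    pixel_size_um: 0.25
    n_slices: 11
    noise_sd: 0.05
cutoff:
  cell_type: HUVEC
  cells_per_field_cutoff: 6
groupings: [by_confluency, by_time]
growth:
  seed_density: 100
  doubling_times_hr:
    HUVEC: 33
    ECFC: 26
  times_hr: [4, 24, 48, 72, 96]
  noise: poisson
  seed: 7
save_images: false
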