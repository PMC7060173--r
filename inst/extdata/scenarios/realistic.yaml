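# "Realistic" two-color SMLM scenario: 40% labeling efficiency,
# 5 unspecifically bound labels/um^2 per channel, 1 (red) and 2 (blue)
# false-positive background signals/um^2; otherwise as ideal.yaml.
roi: {x_min: 0, y_min: 0, x_max: 10000, y_max: 10000}
pattern:
  kind: random
  molecule_density: 75
labeling: {efficiency: 0.4, ratio: 0.5}
blink_red:
  family: lognormal
  meanlog: 1.1631508098056809
  sdlog: 0.8
  frame_assignment: uniform
  n_frames: 10000
blink_blue:
  family: lognormal
  meanlog: 1.1631508098056809
  sdlog: 0.8
  frame_assignment: uniform
  n_frames: 10000
artifacts:
  localization_error_sigma: 30
  unspecific_label_density: 5
  background_density_red: 1
  background_density_blue: 2
  background_blink: {family: geometric, mean: 2}
  drift_total: [0, 0]
  aberration_beta: 0
  aberration_center: [2500, 2500]
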