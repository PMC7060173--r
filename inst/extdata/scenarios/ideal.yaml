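# "Ideal" two-color SMLM scenario: 100% labeling efficiency, no
# unspecific labels, no background. 10 x 10 um^2, 75 molecules/um^2,
# 30 nm localization error, balanced labeling, synthetic SNAP-like
# log-normal blinking.
roi: {x_min: 0, y_min: 0, x_max: 10000, y_max: 10000}
pattern:
  kind: random
  molecule_density: 75
labeling: {efficiency: 1.0, ratio: 0.5}
blink_red:
  family: lognormal
  meanlog: 1.1631508098056809  # log(3.2)
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
  unspecific_label_density: 0
  background_density_red: 0
  background_density_blue: 0
  drift_total: [0, 0]
  aberration_beta: 0
  aberration_center: [2500, 2500]
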