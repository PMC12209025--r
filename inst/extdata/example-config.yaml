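# Example run configuration: keys override the package defaults
# (negrowth::default_config()) block by block.
maze:
  arm_length: 50        # cm, centre boundary to arm tip
  arm_width: 10         # cm
  centre_size: 10       # cm, square side
  grid_resolution: 1    # cm per segment
  open_axis: x
discretisation:
  interpolate: true     # fill segments crossed between samples
  speed_warn: 25        # cm/s; faster samples are flagged
simulation:
  n_subjects: 10
  duration: 300         # s
  noise: true
sampler:
  chains: 4
  warmup: 1000
  iter: 1000
  thin_time: 5          # fit every 5th second (exact under the increment model)
effects:
  rope_scale: proportion   # +/-0.18 on the proportion (percent/100) scale
  hdi_level: 0.95
  basis: 10
  n_draws: 4000
  time_step: 1
classification:
  open_floor: 5         # percent open NEG under which exploration counts as absent
  gap_cuts: [25, 50, 75]
seed: 1
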