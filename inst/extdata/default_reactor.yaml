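# Default configuration of the capillary droplet reactor twin.
# Any omitted entry falls back to the package default; units as noted.

geometry:
  tubing_length: 190          # cm
  inner_diameter: 0.51        # mm
  droplet_junction_pos: 15    # cm
  injection_junction_pos: [100, 130, 160]  # cm
  detector_pos: 190           # cm

flows:
  q_aqueous_1: 10             # uL/min, iron precursor stream
  q_aqueous_2: 10             # uL/min, ammonia stream
  q_oil: 10                   # uL/min, carrier oil
  q_gold_max: 30              # uL/min, injection ceiling

calibration:
  shell_slope: 0.36082474     # nm per uL/min (3.5 nm at 9.7 uL/min)
  response_center: 9.7        # uL/min
  response_amplitude: 0.5     # decadic absorbance units
  response_width: 5.0         # uL/min
  baseline_transmission: 0.95 # fraction of full scale
  trace_noise_sd: 0.01        # fraction of full scale
  droplet_frequency: 60       # droplets/min
  secondary_droplet_limit: 30 # uL/min
  side_product_onset: 12      # uL/min
  core_diameter_mean: 5.8     # nm
  core_diameter_sd: 1.4       # nm
  shell_thickness_sd: 0.6     # nm

detector:
  sampling_rate: 50           # Hz
  window_min: 2               # minutes per collection window

optimizer:
  guess: 5                    # uL/min
  step: 2                     # uL/min
  min_step: 0.1               # uL/min
  bounds: [1, 30]             # uL/min
  max_iterations: 50
  contraction: 0.5
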