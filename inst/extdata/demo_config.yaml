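# Demonstration run: split-fed six-compartment baffled reactor (6:3:1 split)
reactor:
  n_compartments: 6
  total_volume: 17.88    # litres
  total_flow: 0.37       # L/h, nominal HRT 48.3 h
  feed_split: [0.6, 0.0, 0.3, 0.0, 0.1, 0.0]
tracer:
  injected_mass: 10      # mg, enters with the feed split
  sampling_interval: 6   # hours
  duration_multiple: 3   # sample to theta = 3
  noise_cv: 0
rtd:
  dispersion_method: small-dispersion
  dead_space_upper: 2
cod:
  feed_cod: 4250         # mg/L
  removal_rates: [0.08, 0.05, 0.04, 0.03, 0.05, 0.01]  # 1/h per compartment
gel:
  n_lanes: 6
  n_bands: 10
  concentration_parameter: 1.0
  rng_seed: 42
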