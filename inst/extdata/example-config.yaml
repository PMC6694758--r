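# Example analysis configuration: track geometry, generator settings,
# and analysis parameters shared by all pipeline stages.
track:
  approach_length_m: 120
  arc_length_m: 100
  radius_m: 100
  c1_length_m: 50
  exit_length_m: 100
generator:
  n_participants: 18
  n_bends: 6
  hz: 20
  gf_sigma_deg: 1.8
analysis:
  coverage: 0.9995
  window_bins: 63
  split_penalty: 6
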