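# Demo run configuration; load with load_run_config() or pass to the CLI
# via --config. Fields mirror default_run_config().
seed: 1
cut_rate: 0.2
kd_factor: 0.25
reference:
  n_transposons: 20
  transposon_length: [400, 1200]
enzyme:
  CA: 1.0
  CC: 0.35
  AA: 0.35
  GU: 0.05
  UA: 0.25
maturation:
  p_load: 0.5
  p_mature: 0.8
  p_pingpong: 0.7
depths:
  cp: 3000
  pcp: 2000
  pirna: 3000
  pirna_kd: 3000
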