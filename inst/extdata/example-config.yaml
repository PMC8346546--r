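# Example configuration for the mgfabm command-line tool.
#
#   mgfabm simulate --config example-config.yaml --seed 1 --replicates 5 --out out/
#   mgfabm sa       --config example-config.yaml --data fixture.csv --seed 1 --out out/
#
protocol:
  mg: [0.8, 3, 6, 12, 60]   # one culture condition per concentration (mM)
  n_seed: 180               # cells seeded on the z = 0 surface
  days: 3
  measure_days: [3]
  observables: [live_count, viability]
  world_dim: [30, 30, 8]
  medium_change: true

# optional parameter overrides (defaults otherwise)
params:
  gP0: 0.30
  gM0: 0.010

# used by the `sa` and `calibrate` subcommands
calibration:
  pool: [gP0, aP, gM0, aM, aD]
  k_top: 5
  n_runs: 500
  n_keep: 20
  max_iter: 3
  screen_replicates: 2
  screen_min_runs: 32
  min_viability: 50
  priors:
    gP0: [0.05, 0.35]
    aP: [0.5, 2.5]
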