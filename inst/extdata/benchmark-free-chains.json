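{
  "_comment": "LONG-RUNNING production-scale benchmark: free (unconfined) flexible homopolymer, N = 500. Reference spans: 38.08 (flexible, N = 500), 91.77 (semi-flexible, N = 500, set blocks = semiflexible); diblock N = 1000 block spans 40.06 / 93.66 (set N = 1000, blocks = diblock). Run with S_p/d_p keys removed via run_experiment on a config without an array. Do not run in CI.",
  "N": 500,
  "blocks": "flexible",
  "b": 20,
  "S_p": 12,
  "n_y": 8,
  "n_z": 8,
  "dt": 0.005,
  "T": 1,
  "thermostat": "nose_hoover",
  "gamma_or_tau": 0.1,
  "n_equil": 50000000,
  "n_prod": 200000000,
  "sample_interval": 10000,
  "seed": 1,
  "replicas": 3,
  "orientation": "parallel"
}
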