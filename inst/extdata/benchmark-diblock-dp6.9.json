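{
  "_comment": "LONG-RUNNING production-scale benchmark (days of CPU): N = 1000 symmetric diblock in the moderate-confinement array d_p = 6.9, S_p = 12. Reference observables at this geometry: occupation numbers 26.7 (whole) / 21.5 (semi-flexible block) / 8.05 (flexible block); S(q) hump at q = 2*pi/S_p. Do not run in CI.",
  "N": 1000,
  "blocks": "diblock",
  "b": 20,
  "S_p": 12,
  "d_p": 6.9,
  "n_y": 16,
  "n_z": 16,
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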