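{
  "bprw": {
    "b": 0.05,
    "p": 0.5,
    "w": 0.5
  },
  "attractant": {
    "D": 200,
    "T_prod": 30,
    "q": 1,
    "geometry": "margin_ring",
    "decay": 0
  },
  "link": {
    "K_d": 0.1,
    "l_sense": 10,
    "s": 11,
    "b0": 0.05,
    "b_max": 0.85
  },
  "desens": {
    "C_trigger": 0.002,
    "tau_refractory": 120,
    "enabled": false
  },
  "speed": {
    "shape": 2,
    "mean": 3
  },
  "seq_decay": 0.03,
  "n_cells": 300,
  "duration": 100,
  "dt": 1
}
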