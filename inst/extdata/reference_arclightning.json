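{
  "n_states": 4,
  "k_f0": [0.56632862498702, 0.689346312360252, 0.0472962355094201],
  "k_b0": [4.45063086936236, 0.335064558602589, 0.033805760862003],
  "z": [1.18193311565377, 0, 0],
  "delta": [0.5, 0.5, 0.5],
  "brightness": [1, 1, 1, 0.25],
  "temperature_C": 19,
  "name": "arclightning"
}
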