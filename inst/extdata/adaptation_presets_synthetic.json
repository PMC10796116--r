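{
  "26C-evolved": {
    "E_a_multiplier": 1.15,
    "c_tag_max": 4.5e7,
    "k_ref_multiplier": 1.0,
    "T_d": 310.15
  },
  "32C-evolved": {
    "E_a_multiplier": 1.25,
    "c_tag_max": 7.5e7,
    "k_ref_multiplier": 0.7,
    "T_d": 312.15
  },
  "32C-evolved-ctag": {
    "c_tag_max": 7.5e7
  }
}
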