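{
  "none": {
    "APC": 0,
    "IL12_e": 0,
    "IL4_e": 0
  },
  "proTh1": {
    "APC": 1,
    "IL12_e": 1,
    "IL4_e": 0
  },
  "proTh2": {
    "APC": 1,
    "IL12_e": 0,
    "IL4_e": 1
  }
}
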