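{
  "Th0": {
    "TBET": 0,
    "GATA3": 0,
    "IFNG": 0,
    "IL4": 0
  },
  "Th1": {
    "TBET": 1,
    "GATA3": 0,
    "IFNG": 1
  },
  "Th2": {
    "TBET": 0,
    "GATA3": 1,
    "IL4": 1
  }
}
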