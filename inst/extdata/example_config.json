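{
  "populations": {
    "H1": ["H1_1", "H1_2"],
    "H2": ["H2_1", "H2_2"],
    "H3": "H3_1",
    "H4": "H4_1"
  },
  "block_size": 1000000,
  "error_trio": {
    "T": "H1_1",
    "R": "H1_2",
    "O": "H4_1"
  }
}
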