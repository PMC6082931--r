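{
  "name": "both_on",
  "input_values": {
    "SIG1": 1,
    "SIG2": 1,
    "MOD_IN": 0
  },
  "t_end": 200
}
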