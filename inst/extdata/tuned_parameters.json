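{
  "defaults": {
    "n": 3,
    "k": 0.5,
    "tau": 1
  },
  "edges": [
    {
      "source": "PTPRC",
      "target": "LYN",
      "n": 20,
      "k": 0.9
    },
    {
      "source": "PTPN6",
      "target": "BCR",
      "n": 32,
      "k": 0.9
    },
    {
      "source": "PTPN11",
      "target": "BCR",
      "n": 32,
      "k": 0.9
    },
    {
      "source": "FCGR2B",
      "target": "BCR",
      "n": 1,
      "k": 0.9
    },
    {
      "source": "INPP5D",
      "target": "PIP2_2",
      "n": 32,
      "k": 0.9
    }
  ],
  "nodes": [
    {
      "name": "LYN",
      "tau": 10
    },
    {
      "name": "PIP2_2",
      "tau": 16
    }
  ]
}
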