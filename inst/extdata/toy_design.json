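{
  "model": "toy_network.tsv",
  "dialect": "tabular",
  "compress": false,
  "seed": 1,
  "design": {
    "objectives": [
      {"name": "R4_yield", "numerator": "R4", "role": "product_min_yield"}
    ],
    "reference": ["R1", "R2", "R3"]
  },
  "pso": {
    "particles": 4,
    "iterations": 15,
    "stagnation_window": 8,
    "max_cardinality": 5
  }
}
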