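{
  "sim": {
    "n_events": 250,
    "ir_fraction": 0.6,
    "seed": 7
  },
  "min_reads": 10,
  "rna_map": {
    "pattern": "YNYYRAY",
    "width": 150,
    "smooth": 15
  }
}
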