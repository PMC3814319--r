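{
  "bw4": {
    "window_start": 77,
    "window_end": 83,
    "patterns": ["^.{6}R$"]
  },
  "c1_c2_residue": 80,
  "c1_aa": "N",
  "c2_aa": "K",
  "hla_b_c1_exceptions": ["B*46:01", "B*73:01"],
  "a3_11_allele_groups": ["A*03", "A*11"]
}
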