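{
  "id": "HLA",
  "genes": ["HLA-A", "HLA-B", "HLA-C"],
  "framework": [true, true, true],
  "aln_len": [1119, 1119, 1119],
  "leader_aa": [24, 24, 24],
  "name_prefix": ["A", "B", "C"],
  "cen_tel_boundary_after": null
}
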