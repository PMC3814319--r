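{
  "id": "KIR",
  "genes": ["KIR3DL3", "KIR2DL2", "KIR2DL3", "KIR2DL1", "KIR2DL4", "KIR3DL1", "KIR3DL2"],
  "framework": [true, false, false, false, true, false, true],
  "aln_len": [843, 843, 843, 843, 843, 843, 843],
  "leader_aa": [21, 21, 21, 21, 21, 21, 21],
  "name_prefix": ["KIR3DL3", "KIR2DL2", "KIR2DL3", "KIR2DL1", "KIR2DL4", "KIR3DL1", "KIR3DL2"],
  "cen_tel_boundary_after": "KIR2DL1"
}
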