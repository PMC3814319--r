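{
  "rules": [
    {"kir_gene": "KIR2DL2", "epitopes": ["C1"],
     "hla_exceptions": ["C*04:01", "C*02:02", "C*05:01"]},
    {"kir_gene": "KIR2DL3", "epitopes": ["C1"], "hla_exceptions": []},
    {"kir_gene": "KIR2DL1", "epitopes": ["C2"], "hla_exceptions": []},
    {"kir_gene": "KIR2DS1", "epitopes": ["C2"], "hla_exceptions": []},
    {"kir_gene": "KIR3DL1", "epitopes": ["Bw4"], "hla_exceptions": []},
    {"kir_gene": "KIR3DL2", "epitopes": ["A3/11"], "hla_exceptions": []}
  ],
  "kir_expression_null": ["KIR3DL1*004"],
  "hla_expression_null": []
}
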