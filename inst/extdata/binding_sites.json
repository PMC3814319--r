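{
  "HLA-A": {
    "peptide_B_pocket": [7, 9, 24, 25, 34, 45, 63, 66, 67, 70, 99],
    "peptide_F_pocket": [77, 80, 81, 84, 95, 114, 116, 123, 143, 146, 147],
    "TCR": [62, 65, 69, 72, 76, 151, 154, 155, 157, 158, 163, 166],
    "KIR": [],
    "LILR": [193, 194, 195, 196, 197],
    "CD8": [223, 224, 225, 226, 227, 228, 229]
  },
  "HLA-B": {
    "peptide_B_pocket": [7, 9, 24, 25, 34, 45, 63, 66, 67, 70, 99],
    "peptide_F_pocket": [84, 95, 114, 116, 123, 143, 146, 147],
    "TCR": [62, 65, 69, 72, 76, 151, 154, 155, 157, 158, 163, 166],
    "KIR": [77, 78, 79, 80, 81, 82, 83],
    "LILR": [193, 194, 195, 196, 197],
    "CD8": [223, 224, 225, 226, 227, 228, 229]
  },
  "HLA-C": {
    "peptide_B_pocket": [7, 9, 14, 24, 25, 34, 45, 49, 63, 66, 67, 70, 99],
    "peptide_F_pocket": [84, 95, 114, 116, 123, 143, 146, 147],
    "TCR": [62, 65, 69, 72, 76, 151, 154, 155, 157, 158, 163, 166],
    "KIR": [73, 77, 78, 79, 80, 81, 82, 83],
    "LILR": [193, 194, 195, 196, 197],
    "CD8": [223, 224, 225, 226, 227, 228, 229],
    "membrane_proximal": [261, 273, 311, 313, 332, 345]
  },
  "KIR3DL1": {
    "ligand_contact": [31, 44, 86],
    "expression_modulating": [86]
  },
  "KIR2DL1": {
    "ligand_contact": [154, 163, 182],
    "function_modulating": [216, 245]
  }
}
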