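{
  "T cell": ["CD4-positive T cell", "CD8-positive T cell", "Regulatory T cell", "MAIT cell", "Gamma-delta T cell"],
  "B cell": ["Naive B cell", "Memory B cell"],
  "Plasma cell": ["IgA plasma cell", "IgG plasma cell", "IgM plasma cell"],
  "NK cell": [],
  "Monocyte": ["Classical monocyte", "Non-classical monocyte"],
  "Dendritic cell": ["cDC", "pDC"],
  "Mast cell": []
}
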