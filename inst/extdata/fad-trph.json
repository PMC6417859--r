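{
  "name": "FAD-TrpH",
  "comment": "Flavin anion / tryptophan cation radical pair; the three nitrogens with the largest isotropic hyperfine couplings (DFT values, in microtesla).",
  "nuclei": [
    {"label": "N5",  "spin": 1, "coupling_uT": 523, "electron": "A"},
    {"label": "N10", "spin": 1, "coupling_uT": 189, "electron": "A"},
    {"label": "N1",  "spin": 1, "coupling_uT": 322, "electron": "B"}
  ]
}
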