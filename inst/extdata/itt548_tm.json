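{
  "name": "TM",
  "note": "Complex medium template for the iTT548 genome-scale model: glucose, trehalose and amino acids as carbon sources. Uptake rates are nominal placeholders for the measured exponential-phase rates.",
  "bounds": {
    "EX_GLC": [-10, 1000],
    "EX_TRE": [-2, 1000],
    "EX_O2": [-10, 1000],
    "EX_L_VAL": [-1, 1000],
    "EX_L_LEU": [-2, 1000],
    "EX_L_ILE": [-1, 1000]
  },
  "unconstrained": ["EX_NH3", "EX_PI", "EX_SO3", "EX_H2O", "EX_FE2", "EX_MG", "EX_H"]
}
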