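{
  "name": "DMM",
  "note": "Glucose minimal medium template for the iTT548 genome-scale model. Exchange ids must match the distributed SBML; the glucose uptake rate is a nominal placeholder and should be replaced by the measured exponential-phase rate.",
  "bounds": {
    "EX_GLC": [-10, 1000],
    "EX_O2": [-10, 1000]
  },
  "unconstrained": ["EX_NH3", "EX_PI", "EX_SO3", "EX_H2O", "EX_FE2", "EX_MG", "EX_H"]
}
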