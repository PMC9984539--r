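{
  "name": "Integrated diagnostic CASH biomarker (proteins + metabolite + miRNAs)",
  "coefficients": {
    "sCD14": -3.37,
    "CRP": 1.47,
    "VEGF": -0.36,
    "IL-10": -0.57,
    "linoleic acid_r": 316.54,
    "miR-20a-5p_r": -6.06,
    "miR-25-3p_r": 5.41,
    "miR-486-5p_r": 1.26
  },
  "intercept": 0,
  "units": {
    "sCD14": "ng/ml",
    "CRP": "ng/ml",
    "VEGF": "pg/ml",
    "IL-10": "pg/ml",
    "linoleic acid_r": "ratio of total signal",
    "miR-20a-5p_r": "relative expression (delta Cq)",
    "miR-25-3p_r": "relative expression (delta Cq)",
    "miR-486-5p_r": "relative expression (delta Cq)"
  }
}
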