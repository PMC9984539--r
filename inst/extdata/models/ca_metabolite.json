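{
  "name": "Diagnostic CA biomarker (five plasma metabolites, ratio levels)",
  "coefficients": {
    "linoleic acid": 858.65,
    "glycocholic acid": 1005.39,
    "hydroxypalmitic acid": 1091.07,
    "urobilin": -1857.99,
    "7a-hydroxy-3-oxo-4-cholestenoic acid": -2145.29
  },
  "intercept": 0.07,
  "units": {
    "linoleic acid": "ratio of total signal",
    "glycocholic acid": "ratio of total signal",
    "hydroxypalmitic acid": "ratio of total signal",
    "urobilin": "ratio of total signal",
    "7a-hydroxy-3-oxo-4-cholestenoic acid": "ratio of total signal"
  }
}
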