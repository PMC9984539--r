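{
  "name": "L(non-aggressive disease): three plasma metabolites, ratio levels",
  "coefficients": {
    "cis-9-hexadecenoic acid": 3682.02,
    "1-palmitoyl-sn-glycero-3-phosphocholine": -19165.94,
    "bilirubin": 962.10
  },
  "intercept": -0.48,
  "units": {
    "cis-9-hexadecenoic acid": "ratio of total signal",
    "1-palmitoyl-sn-glycero-3-phosphocholine": "ratio of total signal",
    "bilirubin": "ratio of total signal"
  }
}
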