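{
  "name": "L(familial-CA): single plasma metabolite, ratio level",
  "coefficients": {
    "decanoyl-L-carnitine": 1236.91
  },
  "intercept": -0.37,
  "units": {
    "decanoyl-L-carnitine": "ratio of total signal"
  }
}
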