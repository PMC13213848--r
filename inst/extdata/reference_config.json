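{
  "n_pos": 18,
  "n_neg": 20,
  "separation": 1.81238760487365,
  "seed": 1,
  "observers": {
    "model": {
      "loading": 1,
      "link_intercept": -2.6,
      "link_slope": 1.2,
      "tie_propensity": 0,
      "leakage": {
        "BVFTD": 0.06,
        "SD": 0.04,
        "PNFA": 0.04,
        "PSP": 0.06,
        "DLB": 0.25
      },
      "round_digits": 3
    },
    "radiologist1": {
      "loading": 0.431808391042392,
      "link_intercept": -0.8,
      "link_slope": 0.9,
      "tie_propensity": 0.15,
      "leakage": {
        "BVFTD": 0.01,
        "SD": 0.005,
        "PNFA": 0.005,
        "PSP": 0.01,
        "DLB": 0.01
      },
      "round_digits": 3
    },
    "radiologist2": {
      "loading": 0.238367925499418,
      "link_intercept": -0.6,
      "link_slope": 0.8,
      "tie_propensity": 0.2,
      "leakage": {
        "BVFTD": 0.01,
        "SD": 0.005,
        "PNFA": 0.005,
        "PSP": 0.01,
        "DLB": 0.01
      },
      "round_digits": 3
    }
  }
}
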