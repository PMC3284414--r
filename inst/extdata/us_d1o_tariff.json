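{
  "spec": "D1O",
  "coefficients": {
    "M2": -0.146,
    "S2": -0.175,
    "U2": -0.14,
    "P2": -0.173,
    "A2": -0.156,
    "M3": -0.558,
    "S3": -0.471,
    "U3": -0.374,
    "P3": -0.537,
    "A3": -0.45,
    "I3": 0.122,
    "I22": -0.011,
    "I32": 0.015,
    "D1": 0.14
  },
  "se": {
    "M2": 0.008,
    "S2": 0.008,
    "U2": 0.008,
    "P2": 0.008,
    "A2": 0.008,
    "M3": 0.016,
    "S3": 0.016,
    "U3": 0.013,
    "P3": 0.02,
    "A3": 0.015,
    "I3": 0.018,
    "I22": 0.002,
    "I32": 0.003,
    "D1": 0.01
  }
}
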