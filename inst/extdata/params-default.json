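{
  "phi": 0.188,
  "K": 5e7,
  "b0": 2.5e7,
  "MSY": 2e6,
  "epsilon": -1.2,
  "p0": 1500,
  "beta": 1.3,
  "eta": 0.2,
  "omega": 0.005,
  "base_year": 2018,
  "horizon_year": 2050
}
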