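{
  "scenario": "tme",
  "stage": "early",
  "nx": 256,
  "domain": {"value": 400, "unit": "um"},
  "inlet_velocity": {"value": 0.75, "unit": "um/s"},
  "release_rate": 2.5,
  "gamma": 1.0e-12,
  "duration": {"value": 45, "unit": "min"},
  "scheme": "muscl",
  "cfl": 0.5,
  "n_macrophages": 6, "n_tcells": 8, "n_mdsc": 0,
  "density": 1000, "viscosity": 1.0e-3,
  "seed": 1
}
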