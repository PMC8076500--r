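{
  "scenario": "transwell",
  "condition": "OF",
  "per_cell_rate": 986.3,
  "cell_count": 3.6e6,
  "gamma": 2.0e-3,
  "duration": {"value": 72, "unit": "h"},
  "well_radius": {"value": 17.4, "unit": "mm"},
  "insert_radius": {"value": 12.0, "unit": "mm"},
  "insert_wall": {"value": 0.6, "unit": "mm"},
  "membrane_height": {"value": 1.0, "unit": "mm"},
  "height": {"value": 5.0, "unit": "mm"},
  "nr": 58, "nz": 50, "n_steps": 240,
  "counting": "cumulative_flux"
}
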