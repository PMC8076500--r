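{
  "scenario": "benchmark",
  "U": 5.0e-6,
  "lambda": 5.0e-4,
  "M": 1.0,
  "D": 1.0e-8,
  "L": 0.1,
  "t_init": 60,
  "t_end": 2760,
  "variant": "standard",
  "nx": 200,
  "scheme": "quick",
  "cfl": 0.5
}
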