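{
  "geometry": "wand_co1.json",
  "motion": {
    "kind": "lissajous",
    "duration_s": 25,
    "rate_hz": 100
  },
  "noise": {
    "sigma_mm": 0.1,
    "dropout_prob": 0.01
  },
  "distortion": {
    "kind": "none"
  },
  "seed": 42
}
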