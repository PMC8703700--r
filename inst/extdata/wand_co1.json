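{
  "name": "example-wand",
  "markers": [
    "W1",
    "W2",
    "W3",
    "W4",
    "W5"
  ],
  "distance_checks": [
    {
      "id": "bar_long",
      "a": "W1",
      "b": "W3",
      "nominal_mm": 240
    },
    {
      "id": "bar_short",
      "a": "W2",
      "b": "W3",
      "nominal_mm": 80
    },
    {
      "id": "bar_left",
      "a": "W1",
      "b": "W2",
      "nominal_mm": 160
    },
    {
      "id": "stem_full",
      "a": "W2",
      "b": "W5",
      "nominal_mm": 240
    },
    {
      "id": "stem_seg",
      "a": "W4",
      "b": "W5",
      "nominal_mm": 140
    }
  ],
  "angle_checks": [
    {
      "id": "bar_stem_left",
      "a": "W1",
      "vertex": "W2",
      "c": "W5",
      "nominal_deg": 90
    },
    {
      "id": "bar_stem_right",
      "a": "W3",
      "vertex": "W2",
      "c": "W4",
      "nominal_deg": 90
    },
    {
      "id": "bar_vs_stem",
      "a1": "W1",
      "a2": "W3",
      "b1": "W2",
      "b2": "W5",
      "nominal_deg": 90
    }
  ],
  "tolerance_mm": 0.5,
  "tolerance_deg": 0.5,
  "local_positions": {
    "W1": [0, 0, 0],
    "W2": [160, 0, 0],
    "W3": [240, 0, 0],
    "W4": [160, -100, 0],
    "W5": [160, -240, 0]
  }
}
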