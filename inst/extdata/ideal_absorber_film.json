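{
  "materials": {
    "film": { "preset": "ideal_absorber", "kappa_0": 1e-5 }
  },
  "stack": {
    "ambient": "air",
    "layers": [ { "material": "film", "thickness_um": 25 } ],
    "exit": "air"
  },
  "illumination": { "theta_deg": [0, 50, 80] },
  "grid": { "start": 200, "stop": 4500, "step": 1 }
}
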