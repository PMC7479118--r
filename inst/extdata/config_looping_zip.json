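{
  "temperature_C": 23,
  "sampling_rate": 50,
  "noise_sd": 6,
  "noise_model": "white",
  "smoothing_window": 20,
  "seed": 1,
  "handle": {"n_bp": 572, "persistence_length": 45, "stretch_modulus": 1200, "rise_per_bp": 0.338},
  "units": [
    {
      "label": "loop",
      "n_residues": 333,
      "rod_length": 4.0,
      "k0_unfold": 0.00185,
      "dx_unfold": 1.88,
      "k0_refold": 15.7,
      "dx_refold": -13.8,
      "state0": "folded"
    }
  ]
}
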