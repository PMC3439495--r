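{
  "_comment": "Default visible-motion-blur model constants. These are package-chosen, physiologically plausible values (synthetic defaults), not transcribed from any specific measurement; replace any key to match a calibrated model.",
  "speed_px_per_frame": 16,
  "resolution_px_per_deg": 40,
  "sigma_center": 0.03,
  "sigma_surround": 0.18,
  "sigma_mask": 0.10,
  "scale_center": 1,
  "scale_surround": 1,
  "scale_mask": 1,
  "masking_threshold": 0.02,
  "jnd_scale": 50,
  "jnd_exponent": 2,
  "support_sigmas": 4
}
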