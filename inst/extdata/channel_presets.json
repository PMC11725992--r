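{
  "_comment": "Orientation-channel constants per visual-area preset. kappa_phi is the tuning concentration at maximum contrast in double-angle space; c50 and c_exp parameterise the contrast-response saturation. Fields listed under 'placeholder' are SYNTHETIC stand-in values chosen to be physiologically plausible, not transcribed estimates; no result shipped with this package depends on them. The V5 contrast pair (c50 = 0.0817, c_exp = 2.35) is a published value for macaque V5/MT response saturation.",
  "V1": { "kappa_phi": 8.0, "c50": 0.25, "c_exp": 2.4, "placeholder": ["kappa_phi", "c50", "c_exp"] },
  "V2": { "kappa_phi": 6.0, "c50": 0.20, "c_exp": 2.8, "placeholder": ["kappa_phi", "c50", "c_exp"] },
  "V5": { "kappa_phi": 4.0, "c50": 0.0817, "c_exp": 2.35, "placeholder": ["kappa_phi"] }
}
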