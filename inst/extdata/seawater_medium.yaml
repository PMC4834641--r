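# Artificial seawater culture medium with 10 mM CaCl2 (synthetic fixture).
# Elemental mass fractions per kg of medium, major ions only; the exact
# recipe is configuration, not code -- override any entry as needed.
name: seawater_medium
density: 1.025
mass_fractions:
  Na: 0.010780
  Cl: 0.019350
  Mg: 0.001280
  S: 0.000905
  K: 0.000399
  Ca: 0.000401
  H: 0.1082007
  O: 0.8586843
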