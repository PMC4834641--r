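species,radius_pm,note
Ca,100,Shannon effective ionic radius Ca2+ VI-coordinate
Na,102,Shannon Na+ VI
Mg,72,Shannon Mg2+ VI
K,138,Shannon K+ VI
Sr,118,Shannon Sr2+ VI
Cl,181,Shannon Cl- VI
PO3,210,effective thermochemical-style radius for metaphosphate chain unit
PO4,238,thermochemical radius orthophosphate
SO4,258,thermochemical radius sulfate
CO3,178,thermochemical radius carbonate
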