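symbol,Z,atomic_mass
H,1,1.008
B,5,10.81
C,6,12.011
N,7,14.007
O,8,15.999
F,9,18.998
Na,11,22.990
Mg,12,24.305
Al,13,26.982
Si,14,28.085
P,15,30.974
S,16,32.06
Cl,17,35.45
K,19,39.098
Ca,20,40.078
Ti,22,47.867
Mn,25,54.938
Fe,26,55.845
Cu,29,63.546
Zn,30,65.38
Br,35,79.904
Sr,38,87.62
I,53,126.904
Ba,56,137.327
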