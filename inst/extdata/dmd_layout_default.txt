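Fp1 AF3 AF4 Fp2
F7  F3  F4  F8
FC5 Fz  Fz  FC6
T7  FC1 FC2 T8
C3  Cz  Cz  C4
CP5 CP1 CP2 CP6
P3  Pz  Pz  P4
P7  PO3 PO4 P8
O1  Oz  Oz  O2
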