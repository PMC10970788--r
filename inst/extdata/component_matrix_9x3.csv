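descriptor,F1,F2,F3
MolWt,0.97,-0.15,0.19
FpDensityMorgan1,-0.41,0.85,0.06
FpDensityMorgan2,-0.23,0.97,-0.03
FpDensityMorgan3,0.06,0.95,-0.11
HeavyAtomMolWt,0.96,-0.14,0.23
NumValenceElectrons,0.97,-0.16,0.16
TPSA,0.21,-0.04,0.98
pyLabuteASA,0.98,-0.15,0.11
PSA,0.21,-0.04,0.98
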