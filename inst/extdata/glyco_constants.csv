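name,kind,value_da,note
HexNAc,monosaccharide_residue,203.079373,
Hex,monosaccharide_residue,162.052824,
Fuc,monosaccharide_residue,146.057909,
NeuAc,monosaccharide_residue,291.095417,
proton,atomic,1.007276,
water,atomic,18.010565,
carbamidomethyl,modification,57.021464,fixed on C
oxidation,modification,15.994915,variable on M
deamidation,modification,0.984016,variable on N and Q
HexNAc-frag1,fixed_oxonium_mz,138.05,HexNAc secondary fragment; fixed published value
HexNAc-frag2,fixed_oxonium_mz,168.05,HexNAc secondary fragment; fixed published value (common literature value 168.066)
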