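id,role,formula,smiles,name,placeholder
A1,aryl-alkyne,C8H6,C#Cc1ccccc1,phenylacetylene,TRUE
A2,aryl-alkyne,C9H8,C#Cc1ccc(C)cc1,4-ethynyltoluene,TRUE
A3,aryl-alkyne,C8H5NO2,C#Cc1ccc([N+](=O)[O-])cc1,1-ethynyl-4-nitrobenzene,FALSE
A4,aryl-alkyne,C9H8O,C#Cc1ccc(OC)cc1,4-ethynylanisole,TRUE
A5,aryl-alkyne,C8H5F,C#Cc1ccc(F)cc1,1-ethynyl-4-fluorobenzene,TRUE
A6,aryl-alkyne,C8H5Cl,C#Cc1ccc(Cl)cc1,1-chloro-4-ethynylbenzene,TRUE
A7,aryl-alkyne,C8H5Br,C#Cc1ccc(Br)cc1,1-bromo-4-ethynylbenzene,TRUE
A8,aryl-alkyne,C9H8,C#Cc1cccc(C)c1,3-ethynyltoluene,TRUE
A9,aryl-alkyne,C12H14,C#Cc1ccc(C(C)(C)C)cc1,4-tert-butylphenylacetylene,TRUE
A10,aryl-alkyne,C9H8O,C#Cc1cccc(OC)c1,3-ethynylanisole,TRUE
A11,aryl-alkyne,C9H5F3,C#Cc1ccc(C(F)(F)F)cc1,1-ethynyl-4-(trifluoromethyl)benzene,TRUE
A12,aryl-alkyne,C12H8,C#Cc1ccc2ccccc2c1,2-ethynylnaphthalene,TRUE
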