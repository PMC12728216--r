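id,role,formula,smiles,name,placeholder
Y1,2-alkynylpyridine,C7H5N,C#Cc1ccccn1,2-ethynylpyridine,TRUE
Y2,2-alkynylpyridine,C8H7N,C#Cc1cccc(C)n1,2-ethynyl-6-methylpyridine,FALSE
Y3,2-alkynylpyridine,C8H7NO,C#Cc1cc(OC)ccn1,2-ethynyl-4-methoxypyridine,TRUE
Y4,2-alkynylpyridine,C7H4BrN,C#Cc1ccc(Br)cn1,5-bromo-2-ethynylpyridine,FALSE
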