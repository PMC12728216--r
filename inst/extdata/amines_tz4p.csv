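id,role,formula,smiles,name,placeholder
M1,primary-amine,C3H9N,CCCN,n-propylamine,TRUE
M2,primary-amine,C3H8N2O,NCCC(N)=O,3-aminopropanamide,FALSE
M3,primary-amine,C6H13N,NC1CCCCC1,cyclohexylamine,TRUE
M4,primary-amine,C7H9N,NCc1ccccc1,benzylamine,TRUE
M5,primary-amine,C8H11N,C[C@H](N)c1ccccc1,(S)-1-phenylethylamine,FALSE
M6,primary-amine,C8H11N,NCCc1ccccc1,phenethylamine,TRUE
M7,primary-amine,C5H7NO,NCc1ccco1,furfurylamine,TRUE
M8,primary-amine,C6H7N,Nc1ccccc1,aniline,TRUE
M9,primary-amine,C3H9NO,COCCN,2-methoxyethylamine,TRUE
M10,primary-amine,C7H9N,Cc1ccc(N)cc1,4-methylaniline,TRUE
M11,primary-amine,C9H11NO2,NCCC(=O)Oc1ccccc1,phenyl 3-aminopropanoate,FALSE
M12,primary-amine,C8H11NO,COc1ccc(CN)cc1,4-methoxybenzylamine,TRUE
M13,primary-amine,C8H8F3N,NCc1ccc(C(F)(F)F)cc1,4-(trifluoromethyl)benzylamine,TRUE
M14,primary-amine,C9H13NO2,COc1ccc(CN)cc1OC,"3,4-dimethoxybenzylamine",TRUE
M15,primary-amine,C10H12N2O5S,,7-aminocephalosporanic acid,FALSE
M16,primary-amine,C16H19N3O4S,,ampicillin,FALSE
M17,primary-amine,C6H6FN,Nc1ccc(F)cc1,4-fluoroaniline,TRUE
M18,primary-amine,C5H11NO,NCC1CCCO1,tetrahydrofurfurylamine,TRUE
M19,primary-amine,C8H11N,Cc1cc(C)cc(N)c1,"3,5-dimethylaniline",TRUE
M20,primary-amine,C8H9NO2,NCc1ccc2OCOc2c1,piperonylamine,TRUE
M21,primary-amine,C4H9N,NCC1CC1,cyclopropylmethylamine,TRUE
M22,primary-amine,C7H8ClN,NCc1ccc(Cl)cc1,4-chlorobenzylamine,TRUE
M23,primary-amine,C13H13N,NCc1ccc(-c2ccccc2)cc1,4-phenylbenzylamine,FALSE
M24,primary-amine,C5H13N,CC(C)CCN,isopentylamine,TRUE
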