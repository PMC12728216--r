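id,role,formula,smiles,name,placeholder
P1,2-picolylamine,C6H8N2,NCc1ccccn1,2-picolylamine,TRUE
P2,2-picolylamine,C7H10N2,Cc1cccc(CN)n1,(6-methylpyridin-2-yl)methylamine,TRUE
P3,2-picolylamine,C6H7FN2,NCc1ccc(F)cn1,(5-fluoropyridin-2-yl)methylamine,TRUE
P4,2-picolylamine,C7H10N2,Cc1cccnc1CN,(3-methylpyridin-2-yl)methylamine,TRUE
P5,2-picolylamine,C6H7BrN2,NCc1ccc(Br)cn1,(5-bromopyridin-2-yl)methylamine,TRUE
P6,2-picolylamine,C8H12N2,CC(C)(N)c1ccccn1,2-(pyridin-2-yl)propan-2-amine,FALSE
P7,2-picolylamine,C6H7ClN2,NCc1cc(Cl)ccn1,(4-chloropyridin-2-yl)methylamine,TRUE
P8,2-picolylamine,C7H7F3N2,NCc1ccc(C(F)(F)F)cn1,(5-(trifluoromethyl)pyridin-2-yl)methylamine,TRUE
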