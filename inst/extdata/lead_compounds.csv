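compound_id,mic_lo_uM,mic_hi_uM,hc10_uM,hc10_censored,cc50_uM,ti_printed
Re(CO)3(M1Y1),0.39,0.39,73,FALSE,12.4,32
Re(CO)3(M20Y3),0.39,0.78,36,FALSE,8.2,11-21
IrCN(M12Y1),0.20,0.39,81,FALSE,7.3,19-37
IrCN(M8Y4),0.39,0.78,NA,TRUE,38.5,49-99
Mn(CO)3(M19Y1),0.39,0.78,NA,TRUE,11.9,15-31
Mn(CO)3(M22Y1),3.13,6.25,87,FALSE,12.9,2-4
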