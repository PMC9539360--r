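reaction,cofactor,cofactor_mM,DTT_mM,RNaseInh_UmL,NTPs_mM,DNA_nM,PPase_UmL,spermidine_mM,T7_UmL,temperature_C,time_min,pH,yield_gL,sd_gL
1,MgAcetate,60.00,7.09,829,8.57,61,10,2.65,7346,43,263,6.89,12.61,0.82
2,MgAcetate,48.46,3.85,1072,8.81,100,9,1.35,7320,39,98,6.80,10.76,0.47
3,MgAcetate,41.79,5.57,1217,9.89,89,5,2.24,6607,44,120,6.65,11.76,0.66
4,MgAcetate,59.87,9.85,986,8.50,100,2,1.31,6166,40,148,6.78,12.27,0.77
5,MgAcetate,49.28,5.27,1474,7.75,89,8,2.25,7743,44,121,6.67,12.18,0.98
6,MgAcetate,40.00,3.99,1045,9.29,72,7,2.03,7748,44,279,6.60,11.52,0.23
7,MgAcetate,40.00,5.00,1000,7.50,40,1,1.00,7000,37,240,8.00,7.64,0.87
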