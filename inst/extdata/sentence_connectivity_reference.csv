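class,position,area,value,printed_avg
Neg,1,LT,1.4,1.7
Neg,2,LOPER,0.92,1.7
Neg,3,LIPL,1.87,1.7
Neg,4,LOPER,1.03,1.7
Neg,5,LDLPFC,2.08,1.7
Neg,6,LOPER,1.12,1.7
Neg,7,LT,1.48,1.7
Neg,8,LDLPFC,0.44,1.7
Neg,9,RT,0.2,1.7
Neg,10,CALC,0.89,1.7
Neg,11,LSGA,1.84,1.7
Neg,12,LDLPFC,1.03,1.7
Neg,13,LT,1.9,1.7
Neg,14,LDLPFC,0.45,1.7
Neg,15,RT,1.1,1.7
Neg,16,LDLPFC,1.26,1.7
Neg,17,LDLPFC,0.56,1.7
Neg,18,RDLPFC,0.19,1.7
Neg,19,RSGA,0.43,1.7
Neg,20,RIT,1.4,1.7
Aff,1,LT,0.9,0.6
Aff,2,LOPER,0.56,0.6
Aff,3,LIPL,1.01,0.6
Aff,4,LOPER,0.87,0.6
Aff,5,LDLPFC,1.03,0.6
Aff,6,LOPER,0.65,0.6
Aff,7,LT,0.89,0.6
Aff,8,LDLPFC,0.23,0.6
Aff,9,RT,0.1,0.6
Aff,10,CALC,0.43,0.6
Aff,11,LSGA,1.04,0.6
Aff,12,LDLPFC,0.68,0.6
Aff,13,LT,1.1,0.6
Aff,14,LDLPFC,0.17,0.6
Aff,15,RT,0.8,0.6
Aff,16,LDLPFC,0.24,0.6
Aff,17,LDLPFC,0.22,0.6
Aff,18,RDLPFC,0.11,0.6
Aff,19,RSGA,0.32,0.6
Aff,20,RIT,0.9,0.6
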