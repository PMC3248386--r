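parameter,value,class_spaced,class_massed
kA2,1,High,High
kS1a,6,High,High
kD1b,0.3372,High,High
kDAGp,200,High,High
kDAGd,100,High,High
kA1,1e5,High,Medium
kS1b,4,High,Medium
kS3,0.4483,High,Medium
kA3,3,Medium,High
kA4,0.2371,Medium,High
kS3a,6,Medium,High
delayD,10,Medium,High
intPKA,15,Medium,High
kD3,0.0764,Medium,Medium
kD3b,0.1385,Medium,Medium
kS1,0.026,Medium,Medium
kS2,0.2,Medium,Medium
kC1,2,Medium,Medium
kC2,0.1,Medium,Medium
kS4,0.2847,Medium,Medium
kD1,8.0441,Medium,Medium
kD1a,5.33e-8,Medium,Medium
Vm,3.6,Medium,Medium
Kfpka,105,Medium,Medium
intPKC,15,Medium,Medium
kA5,0.003,Low,Medium
kB2a,0.5,Low,Medium
kB2b,6,Low,Medium
kC2b,1,Low,Medium
kB2,0.2,Medium,Low
kD2b,0.4187,Medium,Low
K5HT,1.4e-5,Medium,Low
Kbpka,3,Medium,Low
kB1,0.1276,Low,Low
kD3a,1.6e4,Low,Low
kC2a,1,Low,Low
kD2a,53.1,Low,Low
cAMP_basal,0.005,Low,Low
kS3b,4,Low,Low
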