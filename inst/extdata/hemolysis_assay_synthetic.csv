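label,concentration_uM,replicate,absorbance,role
PBS,0,1,0.078,negative
PBS,0,2,0.082,negative
PBS,0,3,0.080,negative
lysed,0,1,0.846,positive
lysed,0,2,0.851,positive
lysed,0,3,0.855,positive
AuNP_200,200,1,0.086,sample
AuNP_200,200,2,0.090,sample
AuNP_200,200,3,0.083,sample
AuNP_300,300,1,0.091,sample
AuNP_300,300,2,0.087,sample
AuNP_300,300,3,0.094,sample
AuNP_400,400,1,0.095,sample
AuNP_400,400,2,0.089,sample
AuNP_400,400,3,0.098,sample
AuNP_500,500,1,0.099,sample
AuNP_500,500,2,0.104,sample
AuNP_500,500,3,0.096,sample
AuNP_600,600,1,0.108,sample
AuNP_600,600,2,0.101,sample
AuNP_600,600,3,0.112,sample
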