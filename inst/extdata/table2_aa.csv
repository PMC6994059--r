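amino_acid,class,BRP,CWR,FSP,LBR,TWM,VSR
arginine,indispensable,1.75,1.81,2.31,1.41,1.99,2.75
histidine,indispensable,0.88,0.77,0.81,0.59,0.87,1.30
isoleucine,indispensable,1.27,1.33,1.85,0.97,1.55,1.88
leucine,indispensable,2.12,2.20,3.00,1.70,2.57,3.26
lysine,indispensable,2.32,2.20,3.45,1.61,2.31,3.48
methionine,indispensable,0.67,0.73,1.14,0.54,0.79,1.00
phenylalanine,indispensable,1.12,1.17,1.54,0.92,1.43,1.73
threonine,indispensable,1.19,1.18,1.67,0.93,1.32,1.82
tryptophan,indispensable,0.30,0.34,0.48,0.25,0.35,0.44
valine,indispensable,1.40,1.44,2.03,1.15,1.63,2.18
alanine,dispensable,1.67,1.60,2.18,1.31,1.74,2.72
aspartic acid,dispensable,2.70,2.52,4.23,1.99,2.63,4.08
cysteine,dispensable,0.33,0.36,0.43,0.33,0.48,0.48
glutamic acid,dispensable,3.77,4.11,5.86,3.15,6.29,5.86
glycine,dispensable,1.85,1.51,1.75,1.31,1.68,3.08
proline,dispensable,1.26,1.15,1.26,0.99,1.87,2.20
serine,dispensable,0.97,1.00,1.50,0.81,1.23,1.49
tyrosine,dispensable,0.98,1.11,1.34,0.82,1.12,1.54
taurine,dispensable,0.13,0.33,0.34,0.24,0.47,0.24
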