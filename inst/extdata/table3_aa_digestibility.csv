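amino_acid,BRP,CWR,FSP,LBR,TWM,VSR,sem,p_value
arginine,88.3,89.7,89.3,88.8,88.3,90.1,1.046,0.7636
histidine,85.0,87.7,84.2,84.5,85.9,85.7,1.706,0.7528
isoleucine,86.7,87.8,88.3,85.1,86.6,87.9,1.054,0.3388
leucine,87.8,88.3,89.2,86.3,87.6,89.4,0.979,0.3115
lysine,86.7,90.1,90.1,87.2,86.3,87.8,0.954,0.0362
methionine,90.2,90.2,92.7,87.3,89.7,91.1,0.736,0.0021
phenylalanine,86.4,87.0,87.0,85.2,86.9,88.1,1.020,0.5228
threonine,80.4,82.1,83.4,79.0,79.7,83.6,1.546,0.2088
tryptophan,90.9,91.4,93.4,89.3,90.4,92.7,0.739,0.0117
valine,83.9,85.1,86.0,83.0,83.1,86.3,1.311,0.3520
alanine,86.8,87.2,87.1,85.3,84.8,88.2,0.968,0.1923
aspartic acid,85.6,85.4,87.4,83.7,82.4,86.6,0.976,0.0204
cysteine,56.1,59.0,60.8,60.9,59.6,58.5,2.937,0.8664
glutamic acid,84.6,86.6,89.0,84.2,89.8,86.8,1.148,0.0160
glycine,44.7,38.1,34.5,22.1,34.1,47.3,3.748,0.0024
proline,82.0,81.3,79.3,79.9,85.6,85.8,1.303,0.0069
serine,76.3,78.3,81.8,76.9,77.6,80.1,1.977,0.3847
tyrosine,82.1,85.1,85.3,81.8,82.7,83.7,1.094,0.1499
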