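item,BRP,CWR,FSP,LBR,TWM,VSR,sem,p_value
nfe,14.09,43.90,26.18,37.74,31.07,14.77,NA,NA
dm_digestibility,74.0,82.3,67.2,81.0,78.0,67.6,2.210,0.0002
om_digestibility,81.9,89.2,76.4,87.3,81.9,74.1,1.404,<0.0001
ahf_digestibility,87.9,94.6,92.7,85.0,93.1,93.1,0.829,<0.0001
ge_digestibility,86.9,93.7,83.8,89.1,86.6,82.3,0.911,<0.0001
tmen,5.83,4.75,4.71,4.89,4.71,4.62,0.088,<0.0001
me_atwater,5.99,4.47,4.17,4.90,4.24,3.98,NA,NA
me_modified_atwater,5.53,4.02,3.76,4.46,3.83,3.58,NA,NA
me_nrc,5.83,4.37,4.06,4.63,3.96,3.80,NA,NA
tmen_ge,87.1,91.5,87.8,86.8,87.2,84.9,1.547,0.1350
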