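diet_id,dm_pct,ash,cp,ahf,tdf,tif,tsf,ge
BRP,92.89,4.16,31.14,46.40,4.22,3.91,0.30,6.69
CWR,93.92,3.82,29.10,17.27,5.92,4.45,1.47,5.19
FSP,90.82,7.39,38.89,17.43,10.12,7.96,2.16,5.37
LBR,95.18,3.99,24.08,27.02,7.16,4.05,3.11,5.63
TWM,97.38,3.92,34.54,17.98,12.48,8.76,3.72,5.40
VSR,93.88,6.61,47.58,16.50,14.54,9.31,5.23,5.44
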