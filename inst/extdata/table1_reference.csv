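variable,level,kind,c1,c2,c3,c4,s1,s2,s3,s4,f_printed,p_printed
cluster_n,,size,71,84,56,42,,,,,,
htn_history,1,binary,74.6,100.0,42.9,0.0,,,,,95.97,<.001
chol_history,1,binary,100.0,45.2,1.8,28.6,,,,,89.68,<.001
bmi,,continuous,27.8,26.4,24.9,26.8,4.7,4.1,4.5,4.2,4.58,.004
age_years,,continuous,70.7,74.5,73.6,73.9,8.4,6.5,6.9,7.3,3.74,.012
alcohol_decades,,continuous,3.1,3.2,3.1,3.8,2.2,2.2,2.2,2.1,1.10,.351
sex,male,binary,35.2,44.0,44.6,45.2,,,,,0.605,.613
pack_years,,continuous,25.4,28.7,25.3,26.8,30.8,31.4,35.2,33.4,0.18,.910
arms2_genotype,TT,binary,52.1,0.0,83.9,0.0,,,,,101.28,<.001
arms2_genotype,CC,binary,5.6,56.0,3.6,59.5,,,,,39.60,<.001
arms2_genotype,TC,binary,42.3,44.0,12.5,40.5,,,,,6.12,<.001
cfh_genotype,TT,binary,31.0,0.0,35.7,0.0,,,,,20.68,<.001
cfh_genotype,CC,binary,32.4,41.7,21.4,57.1,,,,,5.06,.002
cfh_genotype,CT,binary,36.6,58.3,42.9,42.9,,,,,2.72,.045
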