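variable,mz_yes,mz_no,dz_yes,dz_no
sex_male,24,62,10,22
smoking,9,50,3,22
diabetes,4,55,2,23
hypertension,15,44,8,17
hyperlipidemia,16,43,4,21
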