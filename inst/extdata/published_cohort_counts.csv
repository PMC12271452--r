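variable,level,n
gender,female,3201230
gender,male,2645250
ethnicity,White,2055170
ethnicity,Black,43345
ethnicity,South Asian,63972
ethnicity,Mixed,11447
ethnicity,Other,26097
imd,1,676409
imd,2,666577
imd,3,633123
imd,4,548464
imd,5,472985
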