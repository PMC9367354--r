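trait_complex,trait,unit,ev_LBW,ev_LR,ev_LROG
Production,ecm,kg,0.16,0.16,0.21
Direct health,mastitis,% point,-1.82,-1.73,-1.64
Direct health,lameness,% point,-1.27,-1.22,-1.07
Direct health,ketosis,% point,-1.30,-1.13,-1.01
Direct health,milk_fever,% point,-1.26,-1.26,-1.14
Direct health,metritis,% point,-1.00,-0.95,-0.98
Calving,dystocia,% point,-1.31,-1.23,-1.32
Calving,stillbirth,% point,-2.19,-1.87,-1.76
Calf survival,early_calf_mortality,% point,-1.70,-1.14,-1.30
Calf survival,late_calf_mortality,% point,-3.51,-3.49,-2.63
Cow survival,cow_mortality,% point,-10.77,-11.44,-9.18
Fertility,cr_heifers,% point,0.81,1.04,0.71
Fertility,cr_cows,% point,3.82,1.95,1.96
Fertility,ho_heifers,% point,0.37,0.59,0.51
Fertility,ho_cows,% point,2.74,1.63,1.75
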