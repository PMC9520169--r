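class,ALS,AFR,AR,BB,GM,LS,PMF,PML,OoD
ALS,122,0,0,0,0,0,0,0,14
AFR,0,17,0,0,0,0,0,0,2
AR,0,0,68,0,0,0,0,0,2
BB,0,0,0,222,0,0,0,0,2
GM,0,0,0,0,120,0,0,0,9
LS,0,0,0,0,0,235,0,0,1
PMF,0,0,0,0,0,0,76,0,8
PML,1,0,0,0,0,0,0,166,82
OoD,8,0,1,0,10,24,0,30,1362
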