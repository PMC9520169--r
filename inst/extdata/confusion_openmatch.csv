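class,ALS,AFR,AR,BB,GM,LS,PMF,PML,OoD
ALS,121,0,0,0,0,0,0,0,15
AFR,0,16,0,0,0,0,0,0,3
AR,0,0,69,0,0,0,0,0,1
BB,0,0,0,222,0,0,0,0,2
GM,0,0,0,0,119,0,0,0,10
LS,0,0,0,0,0,235,0,0,1
PMF,0,0,0,0,0,0,77,0,7
PML,5,0,0,0,0,0,0,153,91
OoD,3,0,1,0,5,14,0,41,1371
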