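name,code,known,total,training,validation,test
Angular leafspot,ALS,TRUE,818,498,184,136
Anthracnose fruit rot,AFR,TRUE,188,137,32,19
Anthracnose runner,AR,TRUE,232,129,33,70
Blossom blight,BB,TRUE,1898,1410,264,224
Gray mold,GM,TRUE,1303,1003,171,129
Leaf spot,LS,TRUE,2299,1703,360,236
Powdery mildew fruit,PMF,TRUE,397,236,77,84
Powdery mildew leaf,PML,TRUE,1738,1257,232,249
Unknown or OoD,OoD,FALSE,4216,1346,1435,1435
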