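marker,sample_type,pos_cases,n_cases,neg_controls,n_controls
HOXA11as,DRE,10,36,43,49
HOXA11as,FV,16,30,29,35
KLK10,DRE,17,36,44,49
KLK10,FV,10,30,29,35
GPR147,DRE,18,36,41,49
GPR147,FV,15,30,24,35
GPR62,DRE,20,36,32,49
GPR62,FV,24,30,24,35
HOXD4rc,DRE,11,36,41,49
HOXD4rc,FV,8,30,29,35
HOXD3c,DRE,23,36,31,49
HOXD3c,FV,26,30,16,35
FRZB,DRE,20,36,33,49
FRZB,FV,23,30,26,35
GRASP,DRE,14,36,42,49
GRASP,FV,13,30,31,35
HOXBAS3,DRE,16,36,41,49
HOXBAS3,FV,14,30,32,35
HOXCrcAS3,DRE,7,36,48,49
HOXCrcAS3,FV,6,30,35,35
HOXD8rc,DRE,8,36,45,49
HOXD8rc,FV,10,30,33,35
RASSF1,DRE,22,36,33,49
RASSF1,FV,22,30,26,35
SLC16A5rc,DRE,12,36,45,49
SLC16A5rc,FV,11,30,29,35
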