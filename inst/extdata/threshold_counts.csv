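sample_type,threshold,pos_cases,n_cases,neg_controls,n_controls
DRE,1,36,36,5,49
DRE,2,36,36,9,49
DRE,3,36,36,14,49
DRE,4,34,36,14,49
DRE,5,34,36,19,49
DRE,6,34,36,27,49
DRE,7,33,36,29,49
DRE,8,32,36,32,49
DRE,9,30,36,33,49
DRE,10,29,36,37,49
DRE,11,29,36,38,49
DRE,12,28,36,40,49
DRE,13,26,36,41,49
DRE,14,24,36,44,49
DRE,15,22,36,47,49
DRE,16,20,36,47,49
DRE,17,17,36,48,49
DRE,18,12,36,49,49
DRE,19,10,36,49,49
DRE,20,9,36,49,49
DRE,21,8,36,49,49
DRE,22,8,36,49,49
DRE,23,7,36,49,49
DRE,24,7,36,49,49
DRE,25,7,36,49,49
DRE,26,7,36,49,49
DRE,27,3,36,49,49
DRE,28,2,36,49,49
DRE,29,2,36,49,49
DRE,30,2,36,49,49
DRE,31,1,36,49,49
DRE,32,0,36,49,49
FV,1,30,30,2,35
FV,2,30,30,5,35
FV,3,30,30,7,35
FV,4,30,30,9,35
FV,5,30,30,13,35
FV,6,30,30,16,35
FV,7,29,30,18,35
FV,8,28,30,23,35
FV,9,28,30,25,35
FV,10,28,30,27,35
FV,11,26,30,28,35
FV,12,24,30,30,35
FV,13,23,30,30,35
FV,14,23,30,31,35
FV,15,19,30,32,35
FV,16,15,30,34,35
FV,17,13,30,34,35
FV,18,13,30,34,35
FV,19,12,30,35,35
FV,20,8,30,35,35
FV,21,7,30,35,35
FV,22,5,30,35,35
FV,23,5,30,35,35
FV,24,3,30,35,35
FV,25,2,30,35,35
FV,26,2,30,35,35
FV,27,2,30,35,35
FV,28,2,30,35,35
FV,29,2,30,35,35
FV,30,2,30,35,35
FV,31,2,30,35,35
FV,32,0,30,35,35
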