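label,UP,WA,GL,SQ
UP,805,3,1,3
WA,45,88,8,9
GL,2,11,146,17
SQ,9,13,17,77
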