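label,UP,WA,GL,SQ
UP,803,0,7,2
WA,1,142,3,4
GL,6,1,150,19
SQ,0,8,40,68
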