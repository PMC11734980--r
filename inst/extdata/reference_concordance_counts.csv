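virtual,A,B,C,D
A,507,27,8,2
B,43,2502,99,15
C,13,68,6310,134
D,3,12,94,6295
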