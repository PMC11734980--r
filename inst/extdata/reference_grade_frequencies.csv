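grade,real_frequency,virtual_frequency
A,739,1176
B,3271,5668
C,8237,13987
D,8720,13701
ungraded,NA,20
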