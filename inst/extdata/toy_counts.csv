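provider_id,y,n
A,10,40
B,5,20
C,18,60
D,2,15
E,30,90
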