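provider_id,outcome
A,1
A,0
A,0
A,0
A,0
A,1
A,0
A,1
A,0
A,0
A,0
A,0
A,1
A,0
A,0
A,0
A,0
A,0
A,1
A,0
A,0
A,0
A,1
A,1
A,1
A,0
A,0
A,0
A,1
A,0
A,0
A,0
A,0
A,0
A,0
A,1
A,0
A,1
A,1
A,0
B,1
B,0
B,1
B,0
B,1
B,0
B,0
B,1
B,1
B,1
B,0
B,1
B,1
B,0
B,1
B,0
B,0
B,0
B,0
B,0
B,0
B,0
B,1
B,0
B,0
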