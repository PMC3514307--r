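observed,AA,Aa,aa
AA,96,15,0
Aa,2,87,1
aa,0,14,32
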