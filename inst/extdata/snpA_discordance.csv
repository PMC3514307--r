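observed,AA,Aa,aa
AA,95,1,0
Aa,1,90,0
aa,0,3,23
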