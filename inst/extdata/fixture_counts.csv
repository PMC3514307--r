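fixture,status,AA,Aa,aa
SNP1,case,89,117,70
SNP1,control,156,204,60
SNP2,case,83,145,48
SNP2,control,156,210,54
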