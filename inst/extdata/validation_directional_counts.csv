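locus,n_pairs,Aa_to_AA,Aa_to_aa,AA_to_Aa,AA_to_aa,aa_to_Aa,aa_to_AA
A,213,1,3,1,0,0,0
B,247,15,14,2,0,1,0
C,246,4,7,1,0,0,0
D,249,2,7,0,0,0,0
E,243,7,10,0,0,1,0
F,248,1,0,0,0,0,0
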