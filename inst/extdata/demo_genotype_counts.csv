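locus,genotype,n_cases,n_controls
A,AA,116,186
A,Aa,129,184
A,aa,30,41
B,AA,122,170
B,Aa,119,154
B,aa,31,52
C,AA,87,119
C,Aa,122,193
C,aa,64,82
D,AA,174,262
D,Aa,95,126
D,aa,6,13
E,AA,62,78
E,Aa,146,176
E,aa,62,143
F,AA,204,315
F,Aa,68,82
F,aa,2,13
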