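channel	ID1	ID2	ID7
ins:A:r1	0.025	0	0.025
ins:A:r2_4	0.05	0	0
ins:A:r5+	0.425	0	0
ins:T:r1	0.025	0	0.025
ins:T:r2_4	0.05	0	0
ins:T:r5+	0.425	0	0
ins:CG:r1	0	0	0
ins:CG:r2_4	0	0	0
ins:CG:r5+	0	0	0
ins:MULTI:r1	0	0	0
ins:MULTI:r2_4	0	0	0
ins:MULTI:r5+	0	0	0
del:A:r1	0	0.025	0
del:A:r2_4	0	0.05	0.2
del:A:r5+	0	0.425	0.15
del:T:r1	0	0.025	0
del:T:r2_4	0	0.05	0.2
del:T:r5+	0	0.425	0.15
del:CG:r1	0	0	0.05
del:CG:r2_4	0	0	0.05
del:CG:r5+	0	0	0
del:MULTI:r1	0	0	0.15
del:MULTI:r2_4	0	0	0
del:MULTI:r5+	0	0	0
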