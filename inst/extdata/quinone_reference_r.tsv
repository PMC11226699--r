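strain	r
M.tenebrionis KCTC 72449	0.619
E.rhapontici KCTC 22740	0.490
E.coli K-12 MG1655	-0.464
S.Typhimurium ATCC 14028	-0.347
E.pyrinus KCTC 2590	-0.567
E.teleogrylli SCU-B244	-0.714
P.agglomerans KACC 15275	ND
P.ananatis KACC 22739	ND
P.stewartii KACC 22737	ND
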