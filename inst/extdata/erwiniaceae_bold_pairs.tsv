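a	b
P.beijingensis	W.iniecta
P.beijingensis	W.arboricola
P.beijingensis	W.toletana
W.iniecta	W.arboricola
W.iniecta	W.toletana
W.arboricola	W.toletana
M.theicola	M.alhagi
M.theicola	M.calida
M.theicola	M.gaviniae
M.theicola	M.tenebrionis
M.alhagi	M.calida
M.alhagi	M.gaviniae
M.alhagi	M.tenebrionis
M.calida	M.gaviniae
M.calida	M.tenebrionis
M.gaviniae	M.tenebrionis
E.oleae	E.billingiae
E.aphidicola	E.persicina
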