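strain	PD-1	P.beijingensis	W.iniecta	W.arboricola	W.toletana	M.theicola	M.alhagi	M.calida	M.gaviniae	M.tenebrionis	E.oleae	E.billingiae	E.psidii	E.aphidicola	E.persicina
PD-1	100	81	79	79	79	79	79	79	79	78	76	77	76	77	77
P.beijingensis	79	100	82	81	81	78	78	79	78	77	77	79	76	78	78
W.iniecta	79	80	100	86	86	79	79	79	79	78	77	79	76	79	78
W.arboricola	79	80	83	100	95	78	79	79	79	78	77	79	76	78	78
W.toletana	79	80	83	91	100	78	79	79	78	77	77	79	76	78	78
M.theicola	79	79	79	79	80	100	93	89	88	86	76	77	75	76	76
M.alhagi	79	79	79	79	79	89	100	89	88	86	76	77	75	77	76
M.calida	79	79	79	79	80	84	84	100	94	88	76	77	75	77	76
M.gaviniae	80	79	79	80	80	84	83	90	100	87	76	77	75	77	76
M.tenebrionis	79	79	79	79	79	83	83	85	85	100	75	75	74	76	76
E.oleae	78	79	79	79	81	79	79	79	80	79	100	80	78	78	78
E.billingiae	79	79	80	80	80	79	79	79	79	79	80	100	80	80	79
E.psidii	79	79	79	79	79	78	79	79	78	78	79	80	100	77	78
E.aphidicola	79	79	80	80	80	79	79	80	80	80	80	81	79	100	86
E.persicina	78	79	80	79	79	79	79	79	79	79	79	80	79	83	100
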