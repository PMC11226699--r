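test	PD-1.24h	PD-1.48h	P.beijingensis	W.iniecta	W.toletana	E.oleae
Citrate utilization	V	ND	-	-	+	-
Acetoin production	-	ND	-	+	-	-
Acid from Glycerol	-	+	-	+	+	-
Acid from Erythritol	-	+	-	-	-	-
Acid from d-Arabinose	V	+	-	-	-	+
Acid from l-Xylose	-	-	-	+	+	-
Acid from Amygdalin	-	-	-	+	+	-
Acid from Arbutin	-	-	+	+	+	-
Acid from Esculin ferric citrate	-	-	+	+	+	+
Acid from Salicin	-	-	+	+	+	-
Acid from d-Cellobiose	-	-	-	+	+	-
Acid from d-Maltose	+	+	+	+	+	-
Acid from d-Lactose	-	-	-	+	+	-
Acid from d-Melibiose	+	+	+	+	+	-
Acid from d-Saccharose	-	-	+	+	+	-
Acid from d-Raffinose	-	-	-	+	-	-
Acid from Gentiobiose	+	V	+	+	-	-
Acid from d-Lyxose	-	-	+	-	-	-
Acid from d-Fucose	V	+	-	+	+	-
Acid from d-Arabitol	+	+	-	+	+	+
Acid from Potassium gluconate	-	-	-	V	-	+
Acid from Potassium 2-keto-gluconate	-	-	-	-	-	+
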