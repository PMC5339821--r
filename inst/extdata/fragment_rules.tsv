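cls	kind	chain_role	mode	delta	polarity	required	quant
NdS	lcb	LCB	chain_ion	H-3O-1	-	1	0
NdS	fa	FA	chain_ion	H-1	-	1	1
NS	lcb	LCB	chain_ion	H-3O-1	-	1	0
NS	fa	FA	chain_ion	H-1	-	1	1
NP	lcb	LCB	chain_ion	H-3O-1	-	1	0
NP	fa	FA	chain_ion	H-1	-	1	1
NH	lcb	LCB	chain_ion	H-3O-1	-	1	0
NH	fa	FA	chain_ion	H-1	-	1	1
AdS	lcb	LCB	chain_ion	H-3O-1	-	1	0
AdS	fa	FA	chain_ion	H-1	-	1	1
AS	lcb	LCB	chain_ion	H-3O-1	-	1	0
AS	fa	FA	chain_ion	H-1	-	1	1
AP	lcb	LCB	chain_ion	H-3O-1	-	1	0
AP	fa	FA	chain_ion	H-1	-	1	1
AH	lcb	LCB	chain_ion	H-3O-1	-	1	0
AH	fa	FA	chain_ion	H-1	-	1	1
EOdS	lcb	LCB	chain_ion	H-3O-1	-	1	0
EOdS	fa	FA	chain_ion	H-1O1	-	1	0
EOdS	ester_fa	esterFA	chain_ion	H-1	-	1	1
EOS	lcb	LCB	chain_ion	H-3O-1	-	1	0
EOS	fa	FA	chain_ion	H-1O1	-	1	0
EOS	ester_fa	esterFA	chain_ion	H-1	-	1	1
EOP	lcb	LCB	chain_ion	H-3O-1	-	1	0
EOP	fa	FA	chain_ion	H-1O1	-	1	0
EOP	ester_fa	esterFA	chain_ion	H-1	-	1	1
EOH	lcb	LCB	chain_ion	H-3O-1	-	1	0
EOH	fa	FA	chain_ion	H-1O1	-	1	0
EOH	ester_fa	esterFA	chain_ion	H-1	-	1	1
DAG	fa_nl	FA	neutral_loss	N1H3	+	1	1
TAG	fa_nl	FA	neutral_loss	N1H3	+	1	1
CE	sterol	none	fixed_ion	C27H45	+	1	1
Chol	sterol	none	fixed_ion	C27H45	+	1	1
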