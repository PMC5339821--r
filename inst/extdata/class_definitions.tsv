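code	category	n_chains	adduct	ion_mode	linkage	base
NdS	ceramide	2	acetate	-	N	dS
NS	ceramide	2	acetate	-	N	S
NP	ceramide	2	acetate	-	N	P
NH	ceramide	2	acetate	-	N	H
AdS	ceramide	2	acetate	-	A	dS
AS	ceramide	2	acetate	-	A	S
AP	ceramide	2	acetate	-	A	P
AH	ceramide	2	acetate	-	A	H
EOdS	ceramide	3	acetate	-	EO	dS
EOS	ceramide	3	acetate	-	EO	S
EOP	ceramide	3	acetate	-	EO	P
EOH	ceramide	3	acetate	-	EO	H
CE	neutral	1	ammonium	+	NA	NA
DAG	neutral	2	ammonium	+	NA	NA
TAG	neutral	3	ammonium	+	NA	NA
Chol	sterol	0	ammonium	+	NA	NA
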