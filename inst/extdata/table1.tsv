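rat_id	genotype	sex	age_weeks	diagnosis	loh	loh_type	chromothripsis	ct_chroms	bfb	bfb_chroms	amplified_oncogenes
196	-/-	Male	21	fibrosarcoma	NO	-	NO	-	NO	-	-
198	-/-	Male	13	fibrosarcoma	NO	-	NO	-	NO	-	-
164	-/-	Male	13	hemangiosarcoma	NO	-	NO	-	NO	-	-
174	-/-	Male	18	hemangiosarcoma	NO	-	NO	-	NO	-	-
199	-/-	Male	14	hemangiosarcoma	NO	-	NO	-	NO	-	-
223	-/-	Female	15	hemangiosarcoma	NO	-	NO	-	NO	-	-
261	-/-	Male	12	hemangiosarcoma	NO	-	NO	-	NO	-	-
225	-/-	Male	10	hemangiosarcoma	NO	-	NO	-	NO	-	-
247	-/-	Male	8	hemangiosarcoma	NO	-	NO	-	NO	-	-
201	-/-	Male	20	leiomyosarcoma	NO	-	NO	-	NO	-	-
103	+/-	Male	54	fibrosarcoma	YES	deletion	YES	6	NO	-	-
170	+/-	Male	45	fibrosarcoma	YES	deletion	YES	1	YES	7	Myc
153	+/-	Male	49	leiomyosarcoma	YES	affected by chromothripsis	YES	10,13	YES	9	Vegfa
20	+/-	Female	45	osteosarcoma	YES	gene conversion or copy-neutral SV	NO	-	NO	-	-
82	+/-	Male	45	osteosarcoma	YES	gene conversion	YES	7	NO	-	-
97	+/-	Male	47	osteosarcoma	YES	affected by chromothripsis	YES	3,8,10	NO	-	-
100	+/-	Female	45	osteosarcoma	YES	gene conversion or copy-neutral SV	NO	-	NO	-	-
112	+/-	Female	71	osteosarcoma	YES	affected by chromothripsis	YES	3,10	YES	6,10	Mycn,Alk
118	+/-	Male	41	osteosarcoma	YES	gene conversion	NO	-	NO	-	-
142	+/-	Male	54	osteosarcoma	YES	deletion	YES	5	YES	9	Vegfa
144	+/-	Male	68	osteosarcoma	YES	deletion	NO	-	YES	5,7	Myc
160	+/-	Female	52	osteosarcoma	YES	deletion	NO	-	NO	-	-
202	+/-	Male	34	osteosarcoma	YES	deletion	YES	10,17	YES	14	-
9	+/-	Female	36	rhabdomyosarcoma	YES	gene conversion or copy-neutral SV	YES	6	NO	-	-
125	+/-	Female	46	transitional cell carcinoma	YES	gene conversion or copy-neutral SV	NO	-	NO	-	-
95	+/-	Male	54	ND	YES	deletion	NO	-	NO	-	-
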