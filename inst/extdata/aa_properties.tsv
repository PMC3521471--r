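id	description	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
PALPHA	Alpha-helical conformational propensity P-alpha	1.39	0.74	0.89	1.35	1.01	0.47	0.92	1.04	1.11	1.32	1.21	0.77	0.5	1.29	1.17	0.82	0.76	0.89	1.06	0.95
KUMS000103	Distribution of amino acid residues in the alpha-helices in thermophilic proteins	14.1	0.1	5.7	8.8	5	4.1	2	7.1	7.7	9.1	3.3	3.2	0.7	3.7	5.5	3.9	4.4	5.9	1.2	4.5
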