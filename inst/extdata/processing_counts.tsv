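set	method	identified_peptides	identified_proteins	discarded_peptides	discarded_pct
1	RPA	6676	943	4626	69
2	RPA	8926	1044	6263	70
3	RPA	7269	1040	4962	68
4	RPA	11465	1227	10143	88
5	RPA	14604	1247	11990	82
1	RSPI	10984	1086	2808	26
2	RSPI	12379	1028	3114	25
3	RSPI	11844	1164	3051	26
4	RSPI	14000	1192	4463	32
5	RSPI	22247	1331	8450	38
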