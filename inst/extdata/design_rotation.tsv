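replicate_id	condition	channel	is_reference
1	Control	114	1
1	CsA	115	0
1	Tac	116	0
1	VIVIT	117	0
2	Control	115	1
2	CsA	116	0
2	Tac	117	0
2	VIVIT	114	0
3	Control	116	1
3	CsA	117	0
3	Tac	114	0
3	VIVIT	115	0
4	Control	114	1
4	CsA	115	0
4	Tac	116	0
4	VIVIT	117	0
5	Control	114	1
5	CsA	115	0
5	Tac	116	0
5	VIVIT	117	0
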