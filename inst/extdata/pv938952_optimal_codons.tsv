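amino_acid	codon	rscu_high	n_high	rscu_low	n_low	delta_rscu	star_class
Ala	GCU	2.45	38	1.65	42	0.80	***
Arg	AGA	2.16	31	1.97	65	0.19	*
Gln	CAA	1.46	19	1.34	90	0.12	*
Ile	AUU	1.48	34	1.30	110	0.18	*
Leu	UUA	1.46	17	1.19	64	0.27	*
Leu	UUG	1.63	19	1.53	82	0.10	*
Lys	AAA	1.65	28	1.22	118	0.43	**
Pro	CCU	2.11	19	1.44	57	0.67	***
Ser	AGU	1.77	18	1.00	52	0.77	***
Ser	UCC	1.28	13	1.18	61	0.10	*
Ser	UCG	1.77	18	1.56	81	0.21	*
Thr	ACU	1.95	21	1.44	50	0.51	***
Val	GUA	1.62	15	1.04	40	0.58	***
Val	GUU	1.95	18	1.48	57	0.47	**
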