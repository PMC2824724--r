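mirna	mature_sequence	feeding_larva_miR	feeding_larva_miR_star	spinning_larva_miR	spinning_larva_miR_star	pupa_miR	pupa_miR_star	moth_miR	moth_miR_star	remarks
bmo-mir-2998	AAGAACAGGAUGAGGUAGAUAAA	26	1	9	0	10	0	88	1	
bmo-mir-375	ACCCGAGCGGUCUGAGCAAACU	30	6	4	2	25	11	11	3	
bmo-mir-2766	UCAGUCUUGUCGAAUGGUGGGU	2205	284	2657	166	4588	341	2328	133	
bmo-mir-2999	CUGCGACGGACUAGACGCGCA	20	2	3	0	16	0	107	0	
bmo-mir-2763	AUAUUAUGCUCAUUUCUUUGGAU	15	0	49	0	39	1	199	0	
bmo-mir-2733e-1	UCACUGGGAAUGUAAUAGCUAU	1	0	4	0	273	0	1	0	Family
bmo-mir-2733f	UCACUGGGUAUGUAAUGACAGU	1	0	0	0	83	0	1	0	Family
bmo-mir-2733 g	UCACUGGGUGCAUGAAGAUUG	2	0	0	0	629	2	1	0	Family
bmo-mir-2733a-2	UCACUGGGUGCAUGAUGAUUG	16	0	6	0	2718	2	93	0	Family
bmo-mir-2733b	UCACUGGGUGCGUGAUGAUUGU	0	0	0	0	134	3	0	0	Family
bmo-mir-2733d	UCACUGGGUGUAUGAAGAUUG	0	0	2	0	392	1	5	0	Family
bmo-mir-2733 h	UCACUGGGUGUAUGAUGAUUG	0	0	1	0	163	2	1	0	Family
bmo-mir-3000	CUGCGCUUAGAUGAAGACACUA	53	1	7	0	6	0	6	0	
bmo-mir-3001	UAAGUUGAAAGAAUUGUAGAUUUUGA	4	7	7	8	12	2	14	14	
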