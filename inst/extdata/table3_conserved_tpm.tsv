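mirna	mature_sequence	feeding_larva_miR	feeding_larva_miR_star	spinning_larva_miR	spinning_larva_miR_star	pupa_miR	pupa_miR_star	moth_miR	moth_miR_star
bantam	UGAGAUCAUUGUGAAAGCUAAU	168	3	1189	3	210	0	382	6
bmo-let-7a	UGAGGUAGUAGGUUGUAUAGU	817	4	6277	7	748	8	5149	22
let-7b	UGAGGUAGUAGGUUGUGUGGUU	0	0	0	0	0	0	2	0
let-7c	UGAGGUAGUAGGUUGUAUGGUU	7	0	21	0	0	0	63	0
let-7d	AGAGGUAGUAGGUUGCAUAGUU	0	0	0	0	0	0	4	0
let-7e	UGAGGUAGUAGGUUGUUUAGUU	2	0	52	0	2	0	17	0
let-7f	UGAGGUAGUAGAUUGUAUAGUU	0	0	0	0	0	0	2	0
let-7g	UGAGGUAGUAGUUUGUAUAGUU	0	0	17	0	0	0	9	0
let-7j	UGAGGUAGUAGGUUGUAUAGUU	782	0	6042	0	684	0	4674	0
miR-1	UGGAAUGUAAAGAAGUAUGGAG	6947	0	80224	3	13618	0	14873	0
miR-1b	UGGAAUGUUAAGAAGUAUGUA	1	0	7	0	2	0	0	0
miR-2-1	UAUCACAGCCAGCUUUGAUGAGC	48	1	888	0	127	0	1296	0
miR-2-2	UAUCACAGCCAGCUUUGAUGAGC	48	20	888	377	127	400	1296	1309
miR-2b	UAUCACAGCCAGCUUUGAGGAGC	16	0	131	0	8	0	291	0
miR-2c	UAUCACAGCCAGCUUUGAUGGGC	17	0	176	0	12	0	336	0
miR-2d	UAUCACAGCCAGCUUUGUUGAGU	9	0	131	0	18	0	267	0
miR-7	UGGAAGACUAGUGAUUUUGUUGU	294	1	145	0	75	0	405	6
miR-7b	UGGAAGACUAGUGAUUUUUGUU	2	0	0	0	0	0	4	0
miR-8	UAAUACUGUCAGGUAAAGAUGUC	2488	89	35997	321	3738	901	4513	440
miR-9	UCUUUGGUUAUCUAGCUGUAUGA	265	9	3142	245	946	25	5125	878
miR-9b	UCUUUGGUUACCUAGCUGUAUGA	195	0	2357	0	539	0	3879	0
miR-9c	UCUUUGGUAUUCUAGCUGUAGA	0	0	0	0	2	0	4	0
miR-9d	UCUUUGGUAUCCUAGCUGUAG	103	27	456	76	2334	154	457	67
miR-10	UACCCUGUAGAUCCGAAUUUGU	60	248	297	726	389	2047	265	931
mir-10b	CACCCUGUCAGACCAUACUUGUU	123	4	992	7	746	27	1123	2
miR-11	CAUCACAGUCUGAGUUCUUGC	0	0	0	0	0	0	2	0
miR-11b	CAUCACAGUCAGAGUUCUAGCUA	11	3	41	7	87	3	123	4
miR-12	UGAGUAUUACUUCAGGUACUGGU	163	0	453	0	125	0	39	0
miR-13a	UAUCACAGCCACUUUGAUGUG	3	0	14	0	10	2	4	0
miR-13b	UAUCACAGCCAUUUUUGACGAG	28	0	90	0	42	13	347	19
miR-14	UCAGUCUUUUUCUCUCUCCUA	100	1	169	221	651	20	39	9
miR-31	GGCAAGAAGUCGGCAUAGCUG	36	0	1801	0	634	0	5617	2
miR-33	GUGCAUUGUAGUUGCAUUGC	3	14	17	1013	3	43	0	26
miR-34	UGGCAGUGUGGUUAGCUGGUUG	106	0	35	0	3981	8	22	11
miR-71	UGAAAGACAUGGGUAGUGAGAU	2	3	149	62	48	60	86	22
miR-79	UAAAGCUAGAUUACCAAAGCAU	71	2	131	24	35	7	75	9
miR-87	GUGAGCAAACUUUCAGGUGUGU	14	0	200	3	52	18	181	2
miR-92	UAUUGCACCAGUCCCGGCCUA	5	0	38	3	120	2	88	0
mir-92b	AAUUGCACCAAUCCCGGCCU	3	0	14	21	33	0	58	4
miR-98	UGAGGUAGUAGGUUGUAUUGUU	16	0	107	0	17	0	67	0
miR-98 family	UGAGGUUGAAAGUCGCACA	45	0	3	0	3	0	4	0
miR-99	AACCCGUAGAUCCGAGCUUGUU	0	0	3	0	0	0	11	0
miR-100	AACCCGUAGAUCCGAACUUGUG	128	0	636	3	405	0	3223	0
miR-124	UAAGGCACGCGGUGAAUGCCAA	1	0	3	0	0	0	0	0
miR-133	UUUGGUCCCCUUCAACCAGCUG	15	1	55	0	15	0	11	0
miR-137	UAUUGCUUGAGAAUACACGUAG	1	0	7	0	3	0	11	0
miR-183	UAUGGCACUGGUAGAAUUCACU	3	0	0	0	5	0	41	0
miR-184	UGGACGGAGAACUGAUAAGGGC	611	0	3743	3	2660	5	11507	0
miR-190	AGAUAUGUUUGAUAUUCUUGGUUG	22	8	197	55	47	100	34	9
miR-193	UACUGGCCUGCUAAGUCCCAA	2	0	0	0	8	0	0	0
miR-206	UGGAAUGUAAGGAAGUGUGUGG	0	0	0	0	0	0	2	0
miR-210	UGUGCGUGUGACAGCGGCUA	0	0	0	0	7	0	0	0
miR-228	AAUGGCACUGCAUGAAUUCACGG	1	0	17	0	8	0	28	0
miR-236	UAAUACUGUCAGGUAAUGACGCU	3	0	24	0	7	0	2	0
miR-252	CUAAGUACUAGUGCCGCAGGAG	53	0	463	0	224	0	802	0
miR-263a	AAUGGCACUGGAAGAAUUCAC	1177	2	7376	0	2698	0	22066	2
miR-263b	CUUGGCACUGGGAGAAUUCAC	6	1	31	17	108	10	65	17
miR-274	UUUUGUGACCGACACUAACGGGUAAU	11	0	0	0	0	0	0	0
miR-274b	UUUGUGACCGUCACUAACGGGCA	823	29	83	45	5	0	0	0
miR-275	UCAGGUACCUGAAGUAGCGCGCG	32	1	1856	17	215	0	2083	2
miR-276	AGCGAGGUAUAGAGUUCCUACG	26	27	73	73	58	58	15	17
miR-276a	UAGGAACUUCAUACCGUGCUCU	2108	0	30401	0	22507	0	19446	0
miR-276b	UAGGAACUUAAUACCGUGCUCU	1	0	21	0	25	0	22	0
miR-277	UAAAUGCACUAUCUGGUACGACA	111	0	3336	7	6488	47	1815	2
miR-278	UCGGUGGGAUCUUCGUCCGUU	105	78	283	1421	6648	219	37	860
miR-278	UCGGUGGGAUCUUCGUCCGUUU	103	71	280	1269	6546	179	34	737
miR-278	UCGGUGGGAUUUUCGUCCGUUU	2	0	3	0	159	0	2	0
miR-279	UGACUAGAUCCACACUCAU	16	0	408	3	204	5	608	6
miR-279 family	UGACUAGAUUUUCACUUAUCCU	14	12	33	114	15	25	29	63
miR-281	CUGUCAUGGAGUUGCUCUCUUUA	12	303	17	518	65	916	11	188
miR-282	ACCUAGCCUCUCCUUGGCUUUGUCUGU	192	4	577	7	154	2	60	0
miR-283	UAAAUAUCAGCUGGUAAUUCUGGG	222	2	401	0	169	0	237	0
miR-285	UAGCACCAUUCGAAUUCAGUG	1	0	0	0	10	0	0	0
miR-286	GGACUGGAUCCGGACCCGCGUUCUC	1743	0	332	0	200	0	82	0
miR-305	AUUGUACUUCAUCAGGUGCUCUG	39	1	1863	62	28	2	302	45
miR-306	UCAGGUACUAGGUGACUCUGA	2542	3	3256	10	2662	8	4401	4
miR-307	UCACAACCUCCUUGAGUGAG	50	0	944	7	479	0	1332	2
miR-308	AAUCACAGGAUAAUACUGCGAG	134	6	156	31	47	28	50	22
miR-309	UCACUGGGUGCAUGAUGAUCGU	0	0	0	0	327	0	0	0
miR-317	UGAACACAGCUGGUGGUAUCC	117	0	1358	0	671	0	1367	0
miR-429	UAAUACUGUCUGGUAAUGCCG	0	0	3	0	0	0	0	0
miR-449b	AGGCAGUGUUGUUAGCUGGC	0	0	0	0	8	0	0	0
miR-923	GUAAGCGGAGGAAAAGAAACU	1214	0	294	0	255	0	839	0
miR-927	UUUAGAAUUCCUACGCUUUACC	29	30	131	73	75	50	75	58
miR-932	UCAAUUCCGUAGUGCAUUGCAG	0	0	17	0	0	0	0	0
miR-965	UAAGCGUAUAGCUUUUCCCCUU	16	14	21	283	10	135	6	60
miR-970	UCAUAAGACACACGCGGCU	68	0	453	0	202	0	291	0
miR-980	CAGCUGCCUAGCGAAGGGCAA	54	47	20	69	14	23	17	37
miR-981	UUCGUUGUCGUCGAAACCUGCAA	2	0	10	0	30	0	17	0
miR-989-1	UGUGAUGUGACGUAGUGGAA	2	0	477	0	3494	2	45	0
miR-989-2	UGUGAUGUGACGUAGUGGAA	2	0	477	0	3494	0	45	0
miR-993-1	GAAGCUCGUCUCUACAGGUAUCU	0	19	7	169	8	100	6	164
miR-993-2	AAAGCUCGUCUCUACAGGUAUA	0	19	7	176	8	100	6	181
miR-998	UAGCACCAUGGGAUUCAGCUC	12	0	28	0	110	0	54	0
miR-1000	AUAUUGUCCUGUCACAGCAGU	0	0	0	0	0	0	4	0
miR-1175	UGAGAUUCAACUCCUCCAACUUAA	28	189	14	14	2	0	9	0
miR-1274b	UCCCUGUUCGGGCGCCA	3	0	225	0	13	0	304	0
miR-1308	GCAUGGGUGGUUCAGUGG	2	0	0	0	2	0	0	0
miR-iab-4	ACGUAUACUGAAUGUAUCCUGA	17	1	359	3	42	0	6	0
miR-iab-4-3p	CGGUAUACCUUCAGUAUACGUAAC	1	17	3	356	0	43	0	6
miR-iab-4as-5p	UUACGUAUACUGAAGGUAUACCG	1	0	17	0	0	0	0	0
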