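pt	n_serious	n_nonserious	statistic	test	p_label
Malaise	246	425	204.663	pearson	<0.001
Condition aggravated	361	277	11.561	pearson	0.001
Arthralgia	264	231	20.233	pearson	<0.001
Rash	228	216	26.297	pearson	<0.001
Pneumonia	330	3	186.728	yates	<0.001
Cough	177	119	1.324	pearson	0.250
COVID-19	99	158	66.720	pearson	<0.001
Abdominal pain	193	49	29.356	pearson	<0.001
Illness	72	170	115.819	pearson	<0.001
Nasopharyngitis	113	118	19.840	pearson	<0.001
Influenza	81	106	31.321	pearson	<0.001
Infection	127	36	15.626	pearson	<0.001
Oropharyngeal pain	79	59	1.976	pearson	0.160
Rhinorrhea	61	62	9.539	pearson	0.002
Inflammation	87	23	12.253	pearson	<0.001
C-reactive protein increased	99	10	36.325	pearson	<0.001
Cellulitis	91	2	47.105	yates	<0.001
Nasal congestion	41	44	7.983	pearson	0.005
Lymphadenopathy	59	18	6.140	pearson	0.013
Upper respiratory tract infection	39	38	5.060	pearson	0.024
Viral infection	52	15	6.145	pearson	0.013
Ear infection	30	36	8.746	pearson	0.003
Gastroenteritis	53	4	20.746	yates	<0.001
Disease recurrence	43	14	3.786	pearson	0.052
Serum ferritin increased	45	6	13.950	pearson	<0.001
Pharyngitis streptococcal	14	36	26.338	pearson	<0.001
Concomitant disease aggravated	47	1	23.660	yates	<0.001
Body temperature increased	20	25	6.664	pearson	0.010
SARS-CoV-2 test positive	10	33	29.199	pearson	<0.001
Eosinophilia and systemic symptoms	40	0	NA	fisher	<0.001
Tonsillitis	34	4	10.325	yates	0.001
Deafness	35	1	16.663	yates	<0.001
Pharyngitis	23	12	0.110	pearson	0.740
Transaminases increased	31	3	10.409	yates	0.001
Inflammatory marker increased	24	7	2.765	pearson	0.096
Mouth ulceration	23	7	2.403	pearson	0.121
Blood lactate dehydrogenase increased	28	2	10.582	yates	0.001
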