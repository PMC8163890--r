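strain	family	genome_id	butyrate	propionate	gaba	indole	siderophore_synthesis	siderophore_uptake	antimicrobial	bile_codes	notes
Bacteroides xylanisolvens GGCC_0124	Bacteroidaceae	JABFCE000000000	0	1	1	1	0	0	0	hsd_7a;cgh;oxo_3_5a	Propionate and succinate producer; xylan as C-source
Clostridium butyricum GGCC_0151	Clostridiaceae	JABFCF000000000	1	0	0	0	0	0	0	hsd_7a;cgh;taurine_uptake	Cluster I Clostridium used as probiotic
Clostridium scindens GGCC_0168	Lachnospiraceae	JABFCG000000000	0	0	0	0	0	0	1	dh_7a;dh_3a;hsd_7a;cgh;lcd	Bile acid conversion via 7a-dehydratase; Lactococcin 972-like bacteriocin
Intestinimonas butyriciproducens GGCC_0179	Ruminococcaceae	JABFHK000000000	1	0	0	0	0	0	1	lcd	Butyrate producer; Linocin M18-like bacteriocin
Eubacterium callanderi GGCC_0197	Eubacteriaceae	JABFAG000000000	1	0	1	0	0	0	1	hsd_7a;cgh;sbs	Butanol producer; Linocin M18-like bacteriocin and resistance operon
Extibacter sp. GGCC_0201	Lachnospiraceae	JABFCH000000000	0	0	0	0	0	0	1	dh_7a;dh_7b;lcd	Bile acid conversion via 7a-DH; lanthipeptide synthesis
Akkermansia sp. GGCC_0220	Akkermansiaceae	JABFCI000000000	1	1	1	0	0	0	0	sbs	Distinct species from A. muciniphila ATCC BAA-835 by ANI
Clostridium symbiosum GGCC_0272	Lachnospiraceae	JABFCJ000000000	0	0	1	0	1	0	0	hsd_7a;cgh;lcd;taurine_uptake	Yersiniabactin synthesis operon
Bacteroides uniformis GGCC_0301	Bacteroidaceae	JABFCK000000000	0	1	1	1	0	0	0	cgh;oxo_3_5a;sbs	Positive effect on metabolic and immune dysfunction
Bitterella massiliensis GGCC_0305	Lachnospiraceae	JABFCL000000000	1	0	0	0	0	0	0	hsd_3a;hsd_3b	Bile acid conversion via 3a/3b-HSD
Barnesiella sp. GGCC_0306	Porphyromonadaceae S24-7	JABFCM000000000	0	1	0	1	0	0	0	cgh;oxo_3_5a	Related strains control vancomycin-resistant E. faecium
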