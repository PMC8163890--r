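strain	family	genome_id	butyrate	propionate	gaba	indole	siderophore_synthesis	siderophore_uptake	antimicrobial	bile_codes	siderophore_notes
Megamonas funiformis DSM19343	Selenomonadaceae	742816.3	0	1	0	0	0	1	0		Ferrichrome and Enterobactin uptake
Megamonas hypermegale DSM1672	Selenomonadaceae	1122216.3	0	1	0	0	0	1	0		Ferrichrome uptake
Acidaminococcus intestini DSM21505	Acidaminococcaceae	1120921.3	0	1	0	0	0	0	0
Bacteroides massiliensis DSM17679	Bacteroidaceae	1121098.3	0	1	0	0	0	1	0		Heterologous uptake
Bacteroides stercoris ATCC43183 / DSM19555	Bacteroidaceae	449673.7	0	1	0	1	0	1	0		Heterologous incl. Enterobactin uptake
Barnesiella intestinihominis DSM21032	Porphyromonadaceae	742726.3	0	1	0	0	0	1	0		Heterologous incl. Aerobactin uptake
Faecalibacterium prausnitzii DSM17677	Ruminococcaceae	411483.3	1	0	0	0	0	1	1		Heterologous uptake
Subdoligranulum variabile DSM15176	Ruminococcaceae	411471.5	1	0	0	0	0	0	1
Anaerostipes caccae DSM14662	Lachnospiraceae	411490.6	1	0	0	0	1	1	1	hsd_7a	Heterologous uptake incl. Ferrichrome; Yersiniabactin synthesis
Anaerostipes hadrus DSM3319 / ATCC 29173	Lachnospiraceae	649757.3	1	1	0	0	0	0	0
Clostridium symbiosum ATCC14940	Lachnospiraceae	411472.5	1	0	0	0	0	0	0	hsd_3a;hsd_7a
Akkermansia muciniphila ATCC BAA-835	Akkermansiaceae	349741.6	1	1	0	0	0	1	0		Heterologous uptake
Clostridium scindens ATCC35704	Lachnospiraceae	411468.9	0	0	0	0	0	0	1	dh_7a
Clostridium bolteae ATCC BAA-613	Lachnospiraceae	411902.9	0	0	0	0	1	0	1	hsd_3a;hsd_7a	Siderophore synthesis
Blautia producta DSM2950	Lachnospiraceae	1121114.4	0	1	0	0	0	1	0		Heterologous incl. Ferrichrome uptake
Blautia hydrogenotrophia DSM10507	Lachnospiraceae	476272.21	0	0	0	0	0	0	1	dh_7a;hsd_3b
Marvinbryantia formatexigens DSM14469	Lachnospiraceae	478749.5	0	0	0	0	0	1	0		Heterologous incl. Ferrichrome uptake
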