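name	y_position	ref	mut	fwd_primer	rev_primer	pcr_length	snp_offset	assay
M95	20397832	.	.	.	.	480	.	sanger
F2176	16477410	G	A	AGCAGGTAAGGATCAATAGG	AGTCACTCAGAATAGCAACT	425	211	snapshot
F987	7543143	A	T	CTTTCTTTCTTGTGAGTCTGTC	ATGCGAGTGTAGTTGGAAG	271	140	snapshot
F1252	8492876	C	T	GCTGTCTGAATCTCTACCAT	GGCATGACTAAGGCATCC	377	247	snapshot
F789	6629330	T	A	CACTGTTGCTGCTCCATT	CATCTTCCTGAATATCTGTCTG	407	181	snapshot
F4181	15043403	A	G	GATGCCTTCAGATACTTAGC	CTCTCAGTCCTCATTGTCAT	186	134	snapshot
F2346	16967534	C	T	CCTCATAAGAGCCATTACTTC	ACACATCCTTAGCCATACAT	488	248	snapshot
F761	6136156	A	G	GGTAGTGGAAGGAAGATGAT	AGAAGTTAAGGCTGCTGTT	170	100	snapshot
F2758	18415345	C	T	CTGCTAGTAGACTATTGAAGAC	GTAAGGCATCACCTGTCA	374	225	snapshot
F2411	17184198	C	G	GCTTGTCACTCAATTCTTCA	ACCTTGTAGTGTAGCATCAT	371	237	snapshot
F1399	8762969	C	A	ACCAACTCAACCTCATACTC	CACTTGACCGAAGACCTAG	234	66	snapshot
PK4	.	.	.	.	.	.	.	external
M88	.	.	.	.	.	.	.	external
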