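label	abbrev	name
1	B	Bankssts
2	CACg	Caudal anterior cingulate
3	CMF	Caudal middle frontal
4	CC	Corpus callosum
5	Cu	Cuneus
6	En	Entorhinal
7	Fu	Fusiform
8	IP	Inferior parietal
9	IT	Inferior temporal
10	IstCg	Isthmus cingulate
11	LO	Lateral occipital
12	LOrF	Lateral orbito frontal
13	Lg	Lingual
14	MOrF	Medial orbito frontal
15	MT	Middle temporal
16	PaH	Parahippocampal
17	PaC	Paracentral
18	Ins	Insula
19	Op	Pars opercularis
20	Or	Pars orbitalis
21	Tr	Pars triangularis
22	PerCa	Pericalcarine
23	PoC	Postcentral
24	PoCg	Posterior cingulate
25	PreC	Precentral
26	PreCu	Precuneus
27	RoACg	Rostral anterior cingulate
28	RoMF	Rostral middle frontal
29	SF	Superior frontal
30	SP	Superior parietal
31	ST	Superior temporal
32	SM	Supramarginal
33	FPol	Frontal pole
34	TPol	Temporal pole
35	TrT	Transverse temporal
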