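# Contingency counts (LH = list hits, LT = list total, PH = population hits,
# PT = population total) and fold-enrichment values reported by the
# originating study for the gene groups matching complementary sequences 1
# and 4; fold = (LH/LT)/(PH/PT).
gene_group	category	term	LH	LT	PH	PT	fold
complement_1	UP_KW_PTM	Isopeptide bond	19	70	1569	13044	2.257
complement_1	GOTERM_CC_DIRECT	Nucleoplasm	29	79	3674	21301	2.128
complement_4	INTERPRO	SNF2-related	7	273	34	20806	15.69
complement_4	UP_SEQ_FEATURE	Ion transport	7	280	56	22228	9.923
complement_4	UP_SEQ_FEATURE	Helicase ATP-binding	9	280	117	22228	6.107
complement_4	INTERPRO	Immunoglobulin I-set	12	273	150	20806	6.097
complement_4	GOTERM_CC_DIRECT	Sarcolemma	11	277	141	21301	5.999
complement_4	UP_KW_MOLECULAR_FUNCTION	Helicase	9	168	139	12161	4.687
complement_4	GOTERM_CC_DIRECT	Postsynaptic density	19	277	375	21301	3.896
complement_4	UP_KW_MOLECULAR_FUNCTION	Chromatin regulator	13	168	299	12161	3.147
complement_4	GOTERM_CC_DIRECT	Axon	21	277	516	21301	3.130
complement_4	GOTERM_CC_DIRECT	Neuronal cell body	26	277	659	21301	3.034
complement_4	GOTERM_CC_DIRECT	Dendrite	24	277	626	21301	2.948
complement_4	UP_SEQ_FEATURE	Basic residues	24	280	669	22228	2.848
complement_4	GOTERM_CC_DIRECT	Neuron projection	21	277	582	21301	2.775
complement_4	UP_KW_CELLULAR_COMPONENT	Synapse	20	253	520	17987	2.734
complement_4	UP_SEQ_FEATURE	Acidic residues	29	280	956	22228	2.408
complement_4	GOTERM_CC_DIRECT	Glutamatergic synapse	20	277	663	21301	2.320
complement_4	GOTERM_CC_DIRECT	Cell projection	37	277	1246	21301	2.284
complement_4	GOTERM_CC_DIRECT	Synapse	30	277	1019	21301	2.264
complement_4	GOTERM_CC_DIRECT	Perinuclear region of cytoplasm	24	277	842	21301	2.192
complement_4	GOTERM_CC_DIRECT	Macromolecular complex	26	277	946	21301	2.114
complement_4	UP_SEQ_FEATURE	Basic and acidic residues	139	280	5402	22228	2.043
complement_4	UP_KW_CELLULAR_COMPONENT	Cell projection	34	253	1205	17987	2.006
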