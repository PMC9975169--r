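# epimediate packaged annotation; GRCh37/hg19, 1-based inclusive positions
probe_id	chromosome	position	gene	genic_region	cpg_relation
cg17901584	1	55353706	DHCR24	TSS1500	S_Shore
cg03725309	1	109757585	SARS	genic	S_Shore
cg16246545	1	120255941	PHGDH	genic	S_Shore
cg14476101	1	120255992	PHGDH	genic	S_Shore
cg19693031	1	145441552	TXNIP	3UTR	OpenSea
cg06690548	4	139162808	SLC7A11	genic	OpenSea
cg19494588	5	146195103	PPP2R2B	genic	OpenSea
cg26403843	5	158634085	RNF145	genic	N_Shelf
cg21429551	7	30635762	GARS	genic	S_Shore
cg03068497	7	30635838	GARS	genic	S_Shore
cg19390658	7	30636176	GARS	genic	S_Shore
cg05014727	10	6214016	PFKFB3	genic	OpenSea
cg26262157	10	6214079	PFKFB3	genic	OpenSea
cg07504977	10	102131012		intergenic	N_Shelf
cg11376147	11	57261198	SLC43A1	genic	OpenSea
cg00574958	11	68607622	CPT1A	5UTR	N_Shore
cg09737197	11	68607675	CPT1A	5UTR	N_Shore
cg17058475	11	68607737	CPT1A	5UTR	N_Shore
cg27431877	12	124911924	NCOR2	genic	S_Shore
cg07434438	16	72961899	ZFHX3	genic	OpenSea
cg20544516	17	17717183	SREBF1;MIR33B	genic	S_Shore
cg08129017	17	17728660	SREBF1	genic	S_Shore
cg11024682	17	17730094	SREBF1	genic	S_Shelf
cg22304262	19	47287778	SLC1A5	5UTR	N_Shelf
cg02316713	21	43619559	ABCG1	TSS1500	OpenSea
cg27243685	21	43642366	ABCG1	genic	S_Shelf
cg00222799	21	43655464	ABCG1	genic	Island
cg06500161	21	43656587	ABCG1	genic	S_Shore
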