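rsid	chrom	pos	ref	alt	gene
rs4244285	10	96541616	G	A	CYP2C19
rs4986893	10	96540410	G	A	CYP2C19
rs72552267	10	96535173	G	A	CYP2C19
rs776746	7	99270539	T	C	CYP3A5
rs3745274	19	41512841	G	T	CYP2B6
rs2279343	19	41515263	A	G	CYP2B6
rs2108622	19	15990431	C	T	CYP4F2
rs4149056	12	21331549	T	C	SLCO1B1
rs116855232	13	48611934	C	T	NUDT15
rs869320766	13	48613918	G	A	NUDT15
rs12979860	19	39738787	C	T	IFNL3
rs1057910	10	96741053	A	C	CYP2C9
rs4148323	2	234669144	G	A	UGT1A1
rs111033539	2	234669600	C	T	UGT1A1
rs1800460	6	18139228	C	T	TPMT
rs1142345	6	18130918	T	C	TPMT
rs72554665	X	153762634	G	A	G6PD
rs72554664	X	153763492	C	T	G6PD
rs72554663	X	153764217	C	T	G6PD
rs78655421	7	117171029	G	A	CFTR
rs115545701	7	117120251	C	T	CFTR
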