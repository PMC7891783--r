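gene	allele	functional_class	markers
CYP2C19	*1	normal	
CYP2C19	*2	no_function	rs4244285
CYP2C19	*3	no_function	rs4986893
CYP2C19	*6	no_function	rs72552267
CYP3A5	*1	normal	
CYP3A5	*3	no_function	rs776746
CYP2B6	*1	normal	
CYP2B6	*6	decreased	rs3745274;rs2279343
CYP4F2	*1	normal	
CYP4F2	*3	decreased	rs2108622
SLCO1B1	*1	normal	
SLCO1B1	*5	decreased	rs4149056
NUDT15	*1	normal	
NUDT15	*2	no_function	rs116855232;rs869320766
NUDT15	*3	no_function	rs116855232
IFNL3	ref	normal	
IFNL3	T	risk	rs12979860
CYP2C9	*1	normal	
CYP2C9	*3	no_function	rs1057910
UGT1A1	*1	normal	
UGT1A1	*6	decreased	rs4148323
UGT1A1	*37	decreased	rs111033539
TPMT	*1	normal	
TPMT	*3A	no_function	rs1800460;rs1142345
TPMT	*3C	no_function	rs1142345
G6PD	B	normal	
G6PD	Canton	decreased	rs72554665
G6PD	KaiPing	decreased	rs72554664
G6PD	Gaohe	decreased	rs72554663
CFTR	ref	normal	
CFTR	R117H	favorable	rs78655421
CFTR	R74W	favorable	rs115545701
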