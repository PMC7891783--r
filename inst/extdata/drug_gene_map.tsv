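drug	genes	indication_caveat
simvastatin	SLCO1B1	
clopidogrel	CYP2C19	CPIC recommends genotype-guided prescription only in acute coronary syndrome with percutaneous coronary intervention
ibuprofen	CYP2C9	
warfarin	CYP4F2;CYP2C9	
tacrolimus	CYP3A5	
escitalopram	CYP2C19	
citalopram	CYP2C19	
sertraline	CYP2C19	
voriconazole	CYP2C19	
azathioprine	NUDT15;TPMT	
mercaptopurine	NUDT15;TPMT	
carbamazepine	HLA-A;HLA-B	
allopurinol	HLA-B	
abacavir	HLA-B	
efavirenz	CYP2B6	
atomoxetine	CYP2D6	
codeine	CYP2D6	
tramadol	CYP2D6	
peginterferon alfa-2a	IFNL3	
rasburicase	G6PD	
atazanavir	UGT1A1	
celecoxib	CYP2C9	
phenytoin	CYP2C9;HLA-B	
ivacaftor	CFTR	
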