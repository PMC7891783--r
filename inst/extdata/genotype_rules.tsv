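gene	phenotype	definition	pattern	sex_mode	actionable	aggregate_mode	source	external_freq_pct
CYP2C19	Intermediate metabolizer	One normal function allele and one no function allele	normal/no_function	autosomal	TRUE	disjoint	hwe	NA
CYP2C19	Poor metabolizer	Two no function alleles	no_function/no_function	autosomal	TRUE	disjoint	hwe	NA
CYP3A5	Extensive metabolizer	Two functional alleles	normal/normal	autosomal	TRUE	disjoint	hwe	NA
CYP3A5	Intermediate metabolizer	One functional allele and one nonfunctional allele	normal/no_function	autosomal	TRUE	disjoint	hwe	NA
CYP2B6	Intermediate metabolizer	One normal function allele and one decreased function allele	normal/decreased	autosomal	TRUE	disjoint	hwe	NA
CYP2B6	Poor metabolizer	Two decreased function alleles	decreased/decreased	autosomal	TRUE	disjoint	hwe	NA
CYP4F2	Carrier of decreased function allele	Carrier of rs2108622 T allele	carrier:decreased	autosomal	TRUE	disjoint	hwe	NA
HLA-B	*15:02 positive	Heterozygous or homozygous for HLA-B*15:02	carrier:B*15:02	autosomal	TRUE	carrier_union	hwe	NA
HLA-B	*57:01 positive	Heterozygous or homozygous for HLA-B*57:01	carrier:B*57:01	autosomal	TRUE	carrier_union	hwe	NA
HLA-B	*58:01 positive	Heterozygous or homozygous for HLA-B*58:01	carrier:B*58:01	autosomal	TRUE	carrier_union	hwe	NA
SLCO1B1	Intermediate function	TC genotype at rs4149056	normal/decreased	autosomal	TRUE	disjoint	hwe	NA
SLCO1B1	Low function	CC genotype at rs4149056	decreased/decreased	autosomal	TRUE	disjoint	hwe	NA
NUDT15	Intermediate metabolizer	One normal function allele and one no function allele	normal/no_function	autosomal	TRUE	disjoint	hwe	NA
NUDT15	Poor metabolizer	Two no function alleles	no_function/no_function	autosomal	TRUE	disjoint	hwe	NA
IFNL3	Unfavorable response genotype	Carrier of rs12979860 T allele	carrier:risk	autosomal	TRUE	disjoint	hwe	NA
CYP2D6	Ultrarapid metabolizer	Carrier of duplications of functional alleles	carrier:increased	autosomal	TRUE	disjoint	external	3.3
CYP2D6	Intermediate metabolizer	One decreased function and one no function allele	decreased/no_function	autosomal	TRUE	disjoint	external	8.54
CYP2D6	Poor metabolizer	Two no function alleles	no_function/no_function	autosomal	TRUE	disjoint	external	0.4
CYP2C9	Intermediate metabolizer	One normal function allele and one no function allele	normal/no_function	autosomal	TRUE	disjoint	hwe	NA
CYP2C9	Poor metabolizer	Two no function alleles	no_function/no_function	autosomal	TRUE	disjoint	hwe	NA
UGT1A1	Poor metabolizer	Two decreased function alleles	decreased/decreased	autosomal	TRUE	disjoint	hwe	NA
TPMT	Intermediate metabolizer	One normal function allele and one no function allele	normal/no_function	autosomal	TRUE	disjoint	hwe	NA
TPMT	Poor metabolizer	Two no function alleles	no_function/no_function	autosomal	TRUE	disjoint	hwe	NA
HLA-A	*31:01 positive	Heterozygous or homozygous for HLA-A*31:01	carrier:A*31:01	autosomal	TRUE	carrier_union	hwe	NA
G6PD	Deficient (male)	One deficient (class II-III) allele	decreased	x_linked_male	TRUE	x_linked	hwe	NA
G6PD	Deficient (female)	Two deficient (class II-III) alleles	decreased/decreased	x_linked_female	TRUE	x_linked	hwe	NA
CFTR	Favorable response genotype	Homozygous or heterozygous for CFTR variants in the FDA drug label	carrier:favorable	autosomal	TRUE	disjoint	hwe	NA
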