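gene	transcript_length	oe_constraint	tier
CYP1A2	4586	0.548	level2
CYP2B6	4172	0.631	level1
CYP2C8	3746	1.24	level1
CYP2C9	6281	1.145	level1
CYP2C19	4654	0.772	level1
CYP2D6	4383	0.299	level1
CYP2E1	5066	0.609	level2
CYP3A4	2788	1.039	level1
CYP3A5	4957	0.535	level1
CYP4F2	4732	1.015	level1
CYP1A1	8151	0.744	level2
CYP1B1	3840	0.56	level2
CYP2A6	6751	1.162	level2
CYP2J2	7382	0.549	level2
CYP3A7	5912	1.152	level2
FMO3	4502	1.025	level2
EPHX1	7521	0.435	level2
ADH1A	3673	0.732	level2
ADH1B	5127	0.607	level2
ADH1C	1279	0.8	level2
ALDH2	2585	1.092	level2
NAT1	6345	0.628	level2
NAT2	8322	1.12	level2
GSTM1	2871	1.059	level2
GSTP1	3577	0.726	level2
GSTT1	6981	0.259	level2
GSTA1	1714	1.023	level2
SULT1A1	7620	0.506	level2
UGT1A1	3106	0.887	level1
UGT1A4	1009	1.241	level2
UGT2B7	7559	0.309	level2
UGT2B15	7705	0.826	level2
TPMT	1561	0.296	level1
NUDT15	4462	0.809	level1
DPYD	4364	0.714	level1
MTHFR	2821	0.829	level2
TYMS	5458	1.034	level2
UMPS	5816	0.517	level2
XDH	3733	0.86	level2
AOX1	5676	1.096	level2
MAOA	3161	0.682	level2
MAOB	1063	0.913	level2
COMT	6941	0.313	level2
CES1	5581	0.293	level2
CES2	2722	0.908	level2
BCHE	6658	1.012	level2
CDA	6428	0.975	level2
DCK	1302	0.873	level2
NT5C2	2874	0.376	level2
ITPA	8855	0.913	level2
NQO1	6699	0.662	level2
POR	2774	1.126	level2
CYB5R3	6886	0.725	level2
GGCX	8871	1.065	level2
G6PD	5846	0.922	level1
ABCB1	2285	1.057	level2
ABCB11	5533	0.274	level2
ABCC1	4770	0.673	level2
ABCC2	7315	0.483	level2
ABCC4	5364	0.272	level2
ABCG2	7969	1.119	level2
SLCO1B1	6294	0.288	level1
SLCO1B3	4086	0.729	level2
SLCO1A2	1690	0.769	level2
SLC6A4	992	1.165	level2
SLC19A1	4303	0.92	level2
SLC22A1	4444	0.844	level2
SLC22A2	2399	0.286	level2
SLC28A3	2058	0.984	level2
SLC29A1	5033	0.297	level2
SLC47A1	2252	0.728	level2
ATP7B	5327	0.738	level2
VKORC1	1291	0.653	level1
IFNL3	984	0.493	level1
IFNL4	4213	0.414	level1
ADRB1	3749	1.043	level2
ADRB2	4427	0.904	level2
ACE	3549	1.037	level2
AGTR1	8387	0.387	level2
KCNH2	2202	0.476	level2
KCNE1	4234	0.366	level2
KCNQ1	8232	0.544	level2
SCN5A	6673	0.873	level2
RYR1	15117	1.107	level1
CACNA1S	5643	0.829	level1
CFTR	6132	0.825	level1
HMGCR	5780	0.276	level2
LDLR	6071	0.549	level2
APOE	4301	1.205	level2
LPA	14082	1.134	level2
PTGS1	8747	0.592	level2
PTGS2	6000	0.659	level2
F2	6560	0.779	level2
F5	4143	0.338	level2
PROC	1380	0.619	level2
PROS1	5977	0.435	level2
SERPINC1	1786	0.262	level2
OPRM1	4165	0.816	level2
DRD2	2173	0.383	level2
ANKK1	3094	1.097	level2
HTR2A	2228	0.834	level2
HTR2C	8419	1.094	level2
TNF	4534	0.744	level1
CCHCR1	5978	1.14	level1
EGFR	993	0.835	level2
ERCC1	3278	0.314	level2
XRCC1	6577	0.942	level2
TPH2	7258	0.828	level2
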