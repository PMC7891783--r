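gene	class	freq	reference_class
CYP2C19	no_function	0.3458896499	normal
CYP3A5	normal	0.2475123765	no_function
CYP2B6	decreased	0.2287068007	normal
CYP4F2	decreased	0.224693609	normal
HLA-B	B*15:02	0.0968	other
HLA-B	B*57:01	0.0009004053649	other
HLA-B	B*58:01	0.08917619706	other
SLCO1B1	decreased	0.1386829647	normal
NUDT15	no_function	0.0976941462	normal
IFNL3	risk	0.07032263661	normal
CYP2C9	no_function	0.02734790808	normal
UGT1A1	decreased	0.2253885534	normal
TPMT	no_function	0.01481962117	normal
HLA-A	A*31:01	0.01247784835	other
G6PD	decreased	0.0368	normal
CFTR	favorable	0.0004501012956	normal
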