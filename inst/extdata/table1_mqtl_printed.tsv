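metabolite	locus	H2	R2	pG_printed
Oxalic acid	IWB8786	0.578	11.88	20.55
Oxalic acid	IWB4387	0.578	0.06	0.10
Oxalic acid	IWB14354	0.578	6.60	11.42
Oxalic acid	IWB35367	0.578	11.11	19.22
Oxalic acid	IWB47615	0.578	1.79	3.10
Oxalic acid	IWA6947	0.578	0.13	0.22
Oxalic acid	IWB29877	0.578	0.09	0.16
Oxalic acid	IWB33544	0.578	6.72	11.63
Ornithine	IWB4446	0.27	10.28	38.07
Ornithine	IWB6885	0.27	12.16	45.04
Ornithine	IWB3615	0.27	5.48	20.30
Ornithine	IWB8638	0.27	0.02	0.07
Ornithine	IWB46787	0.27	3.22	11.93
Ornithine	IWA2098	0.27	2.89	10.70
Ornithine	IWB55921	0.27	1.61	5.96
Ornithine	IWA2558	0.27	0.00	0.00
Ornithine	IWB5567	0.27	0.67	2.48
L-Arginine	IWB56221	0.737	12.69	17.22
Pentose alcohol III	IWB242	0.686	22.27	32.46
Pentose alcohol III	IWB65026	0.686	0.29	0.42
Pentose alcohol III	IWB35763	0.686	0.85	1.24
Pentose alcohol III	IWB18115	0.686	1.94	2.83
L-Tyrosine	IWB49741	0.364	17.36	47.69
Oligo II	IWB6807	0.329	14.73	44.77
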