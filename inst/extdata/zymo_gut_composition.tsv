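organism	abbrev	gdna_percent	genome_size_mbp
Faecalibacterium prausnitzii	FP	14	3.09
Veillonella rogosae	VR	14	2.15
Roseburia hominis	RH	14	3.59
Bacteroides fragilis	BF	14	5.21
Prevotella corporis	PC	6	3.01
Bifidobacterium adolescentis	BA	6	2.09
Fusobacterium nucleatum	FN	6	2.18
Lactobacillus fermentum	LF	6	1.905
Clostridioides difficile	CD	1.5	4.29
Akkermansia muciniphila	AM	1.5	2.69
Candida albicans	CA	1.5	14.3
Saccharomyces cerevisiae	SC	1.4	12.1
Methanobrevibacter smithii	MS	0.1	1.85
Salmonella enterica	SEN	0.01	4.76
Enterococcus faecalis	EFA	0.001	2.845
Clostridium perfringens	CP	0.0001	3.31
Escherichia coli JM109	EC1	2.8	4.875
Escherichia coli B-3008	EC2	2.8	4.875
Escherichia coli B-2207	EC3	2.8	4.875
Escherichia coli B-766	EC4	2.8	4.875
Escherichia coli B-1109	EC5	2.8	4.875
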