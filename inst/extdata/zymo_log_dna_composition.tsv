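organism	abbrev	gdna_percent	genome_size_mbp
Listeria monocytogenes	LM	89.1	2.992
Pseudomonas aeruginosa	PA	8.9	6.792
Bacillus subtilis	BS	0.89	4.045
Saccharomyces cerevisiae	SC	0.89	12.1
Escherichia coli	EC	0.089	4.875
Salmonella enterica	SE	0.089	4.760
Lactobacillus fermentum	LF	0.0089	1.905
Enterococcus faecalis	EF	0.00089	2.845
Cryptococcus neoformans	CN	0.00089	19.0
Staphylococcus aureus	SA	0.000089	2.730
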