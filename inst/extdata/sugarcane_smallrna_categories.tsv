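library	category	unique_count	unique_percent	total_count	total_percent
HTD2	antisense_exon	12762	0.50	108151	1.22
HTD2	sense_exon	76415	2.98	651383	7.34
HTD2	miRNA	23950	0.94	1375593	15.49
HTD2	rRNA	58355	2.28	925787	10.43
HTD2	siRNA	59384	2.32	370579	4.17
HTD2	snRNA	2094	0.08	7456	0.08
HTD2	snoRNA	780	0.03	1516	0.02
HTD2	tRNA	13254	0.52	549361	6.19
HTD2	unannotated	2313810	90.35	4888685	55.06
HTD4	antisense_exon	15312	0.47	86674	0.65
HTD4	sense_exon	139293	4.24	814958	6.10
HTD4	miRNA	26926	0.82	3467791	25.95
HTD4	rRNA	63945	1.95	866844	6.49
HTD4	siRNA	61333	1.87	552249	4.13
HTD4	snRNA	4056	0.12	39774	0.30
HTD4	snoRNA	1487	0.05	4854	0.04
HTD4	tRNA	19375	0.59	1399409	10.47
HTD4	unannotated	2951339	89.90	6128310	45.87
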