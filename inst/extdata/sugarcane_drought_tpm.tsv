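day	family	name	sequence	nt	HTD	HTI	LTD	LTI	fc_ht_printed	fc_ht_sig	fc_lt_printed	fc_lt_sig
2	miR164	ssp-miR164	UGGAGAAGCAGGGCACGUGCA	21	95.07	38.57	45.43	95.28	2.46	1	-2.10	1
2	miR394	ssp-miR394	UUGGCAUUCUGUCCACCUCC	20	5.19	6.24	2.30	6.62	-1.20	0	-2.88	1
2	miR397	ssp-miR397	UUGACUGCAGCGUUGAUGAGC	21	1873.63	562.10	799.76	42.42	3.33	1	18.85	1
2	miR399	ssp-miR399seq1	UGCCAAAGGAGAGUUGCCC	19	7.67	5.18	2.89	6.30	1.48	0	-2.18	1
2	miR528	ssp-miR528	UGGAAGGGGCAUGCAGAGGAG	21	4674.10	1445.14	1874.15	1025.19	3.23	1	1.83	0
2	miR1432	ssp-miR1432	UCAGGAAAGAUGACACCAA	19	1687.91	2300.44	1053.92	2583.96	-1.36	0	-2.45	1
4	miR393	ssp-miR393	CUCCAAAGGGAUCGCAUUGAU	21	743.15	808.97	1220.51	582.06	-1.09	0	2.10	1
4	miR394	ssp-miR394	UUGGCAUUCUGUCCACCUCC	20	2.33	5.00	4.64	4.70	-2.14	1	-1.01	0
4	miR397	ssp-miR397	UUGACUGCAGCGUUGAUGAGC	21	940.44	1926.63	858.82	602.07	-2.05	1	1.43	0
4	miR399	ssp-miR399seq1	UGCCAAAGGAGAGUUGCCC	19	0.38	1.61	0.47	2.56	-4.18	1	-5.51	1
4	miR528	ssp-miR528	UGGAAGGGGCAUGCAGAGGAG	21	3717.14	5397.83	182.68	3293.76	-1.45	1	-18.03	1
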