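mirna	target_acc	expectation	target_start	target_end	mirna_fragment	target_fragment	inhibition
ssp-miR164	SCEPRT2048G05.g	1.0	699	718	UGGAGAAGCAGGGCACGUGC	GCAGGUGCCCUGCUUCUCCA	Cleavage
ssp-miR164	SCCCAM1001A03.g	2.5	1774	1792	UGGAGAAGCAGGGCACGUG	CACGUGUCCACCUUCUCCA	Translation
ssp-miR394	SCQGAM2027G09.g	3.0	759	777	UUGGCAUUCUGUCCACCUC	UUGGCAUUCUGUCCACCUC	Cleavage
ssp-miR528	SCJFRT2058D11.g	2.5	101	120	UGGAAGGGGCAUGCAGAGGA	UUCUCGGCAUGCCCCUUCUG	Cleavage
ssp-miR397	SCQSAD1056B07.g	2.5	64	83	UUGACUGCAGCGUUGAUGAG	UUCAUCAACGCCGCACUCAA	Translation
ssp-miR1432	TC134052	3.0	630	648	UCAGGAAAGAUGACACCAA	UUGGUGUUUUCUUCCCUGA	Translation
ssp-miR1432	SCSFFL4085D03.g	3.0	624	642	UCAGGAAAGAUGACACCAA	UUGGUGUUUUCUUCCCUGA	Translation
ssp-miR393	TC120009	1.0	302	320	CUCCAAAGGGAUCGCAUUG	CAAUGCGAUCCCUUUGGAU	Cleavage
ssp-miR399seq1	SCACHR1037A06.g	1.5	463	481	UGCCAAAGGAGAGUUGCCC	GGGUAGUUCUCCUUUGGCA	Cleavage
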