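rearrangement	amino_acid	v_resolved	j_resolved	templates	frame_type
TTAAAAAGCCGAATTTATTCCCTAGAAAAAATAATGCGAAGTCGG	CICISFRWHGSDDAF	TCRBV03-01	TCRBJ02-01	2	In
GATGGACCAGCTAGGCAAACGTTGTACTGCGACATGCCATGATGCACGGGTAAGCCC	CLLDYWNSMGEGRACEYSF	TCRBV05-01	TCRBJ02-02	3	In
TCGCCCCATTGTTGGAGTACCATGTTGTGCTTGTGCGCCCACGAAAAGAATTGC	CTLTWYMGAKSMMHMEHF	TCRBV10-01	TCRBJ01-04	1	In
AGCTGTATTGATAGAAAGGGCTGTGAATCAGCTATC	CAEQNDRKPEMF	TCRBV06-01	TCRBJ02-03	25	In
GGGCCGTTCCGTAACTACCCTGCG	CVVAQQWF	TCRBV28-01	TCRBJ01-06	8	In
GCGTCTACCCCCTGCGTTGGTGAT	CGIKYHSF	TCRBV22-01	TCRBJ02-02	1	In
GTACCCATAGTAAATGCTGCGGTGTTACATATAGCGGCGAGTCCG	CIDFNAQAFIQQADF	TCRBV25-01	TCRBJ02-06	25	In
TTCCCGGGTATCAAGAGACTAGTCGTCGAGTAT	CMINPNQIESF	TCRBV18-01	TCRBJ02-04	1	In
CTAGCAATCGGGAAGCTCTTGCACGTTGGA		TCRBV12-01	TCRBJ01-01	4	Out
AGAGGAAGCATCCTAGCCTTGTATCCAAGA	CASS*RF	TCRBV09-01	TCRBJ02-03	2	Stop
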