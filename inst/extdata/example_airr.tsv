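junction	junction_aa	v_call	j_call	duplicate_count	productive
tcgtagattcgcttgtattatgttgtcgcgaccgaaccgactaga	CICISFRWHGSDDAF	TRBV03-01	TRBJ02-01	2	T
tacatattggttcgcgcctagctaaaagcgaaaaactcttccataacgtcctgccca	CLLDYWNSMGEGRACEYSF	TRBV05-01	TRBJ02-02	3	T
ctgaggaaacagcaccttagtttgtgattagagattcccttcatgcgggctttc	CTLTWYMGAKSMMHMEHF	TRBV10-01	TRBJ01-04	1	T
gttaggtccattcttccatcatatccaaagttctac	CAEQNDRKPEMF	TRBV06-01	TRBJ02-03	25	T
gtagccaatcgtggggaggcctac	CVVAQQWF	TRBV28-01	TRBJ01-06	8	T
aggcaagagcccttcattccgacc	CGIKYHSF	TRBV22-01	TRBJ02-02	1	T
ggcgtcccggatcagtgttaacccgggtgatgtacttaagtctcg	CIDFNAQAFIQQADF	TRBV25-01	TRBJ02-06	25	T
gtatcgggcgaggcttttgccgatccctggaca	CMINPNQIESF	TRBV18-01	TRBJ02-04	1	T
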