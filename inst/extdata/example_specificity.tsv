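cdr3	antigen_epitope	antigen_species	category	disease	source
CICISFRWHGSDDAF	NLVPMVATV	CMV	pathogen	CMV infection	synthetic-db
CLLDYWNSMGEGRACEYSF	GLCTLVAML	EBV	pathogen	EBV infection	synthetic-db
CTLTWYMGAKSMMHMEHF	ELAGIGILTV	HomoSapiens	cancer	Melanoma	synthetic-db
CAEQNDRKPEMF	MVWGPDPLYV	HomoSapiens	autoimmune	Autoimmunity	synthetic-db
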