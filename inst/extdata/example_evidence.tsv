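transcript_id	codon_index	ref	alt	classification_clinvar	classification_hgmd	phenotype_terms	de_novo	n_affected_genotyped_carriers	n_affected_genotyped_noncarriers	n_unaffected_genotyped_carriers
ENST00000999001	101	G	A	Pathogenic	DM	Dravet syndrome	TRUE	1	0	0
ENST00000999001	150	C	T	Likely Pathogenic		early infantile epileptic encephalopathy	FALSE	5	0	1
ENST00000999001	162	A	G		DM	infantile spasms; seizures	FALSE	4	0	0
ENST00000999001	204	T	C	Pathogenic	DM	febrile seizures	FALSE	3	0	1
ENST00000999001	233	G	T	Benign		intellectual disability	FALSE	2	1	2
ENST00000999001	280	C	G	Pathogenic	DM	epileptic encephalopathy	FALSE	4	1	0
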