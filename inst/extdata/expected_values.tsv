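case	operation	expected	tag	oracle
mol1_standin	count_atom_types:F	1	PAPER
mol1_standin	n_atoms	11	TRIVIAL
mol2_standin	count_atom_types:Cl	3	PAPER
mol2_standin	count_atom_types:O	1	TRIVIAL
mol2_standin	count_atom_types:N	1	TRIVIAL
atom_weight(n=1,k=1.0)	atom_weight	0.693147180559945	DERIVED	high-precision log evaluation
atom_weight(n=10,k=0.9)	atom_weight	0.229253475714054	DERIVED	high-precision log evaluation
atom_weight(n=1,k=0.8)	atom_weight	0.470003629245736	DERIVED	high-precision log evaluation
atom_weight(n=2,k=0.8)	atom_weight	0.437734368676950	DERIVED	high-precision log evaluation
expected_masked_counts(C7O2N1,M=2,k=0.9):C	expected_masked_counts	1.110556787780805	DERIVED	normalized log terms
expected_masked_counts(C7O2N1,M=2,k=0.9):O	expected_masked_counts	0.558772656213956	DERIVED	normalized log terms
expected_masked_counts(C7O2N1,M=2,k=0.9):N	expected_masked_counts	0.330670556005239	DERIVED	normalized log terms
inclusion(w=1,1,2;M=1):atom3	inclusion_probabilities_bruteforce	0.5	DERIVED	direct normalization
corpus_spec:C	imbalanced_corpus_spec	0.74	PAPER
corpus_spec:trace_total	imbalanced_corpus_spec	0.04	PAPER
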