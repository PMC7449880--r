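sample_id	gene	event	exons	truncating	confirmed	meth_tested	source
1105-039	BRCA1	exon_duplication	13	TRUE	TRUE	TRUE	table
1105-185	BRCA1	exon_duplication	13	TRUE	TRUE	TRUE	table
1105-207	BRCA1	full_deletion	NA	NA	TRUE	TRUE	table
1105-204	BRCA1	full_deletion	NA	NA	TRUE	TRUE	table
1105-130	BRCA1	full_deletion	NA	NA	TRUE	TRUE	table
1105-R01	BRCA1	full_deletion	NA	NA	TRUE	FALSE	results_text
1105-193	BRCA1	full_duplication	NA	NA	TRUE	TRUE	table
1105-036	BRCA1	full_duplication	NA	NA	TRUE	FALSE	table
1105-018	BRCA1	full_duplication	NA	NA	TRUE	FALSE	table
1105-197	BRCA1	full_duplication	NA	NA	TRUE	FALSE	table
1105-128	BRCA2	full_deletion	NA	NA	TRUE	TRUE	table
1105-144	BRCA2	full_deletion	NA	NA	TRUE	TRUE	table
1105-268	BRCA2	full_deletion	NA	NA	TRUE	TRUE	table
1105-159	BRCA2	full_duplication	NA	NA	TRUE	TRUE	table
1105-192	BRCA2	full_duplication	NA	NA	TRUE	TRUE	table
1105-055	BRCA2	full_duplication	NA	NA	TRUE	FALSE	table
1105-157	BRCA2	full_duplication	NA	NA	TRUE	FALSE	table
1105-181	BRCA2	full_duplication	NA	NA	TRUE	FALSE	table
1105-183	BRCA2	full_duplication	NA	NA	TRUE	FALSE	table
1105-198	BRCA2	full_duplication	NA	NA	TRUE	FALSE	table
1105-229	BRCA2	full_duplication	NA	NA	TRUE	FALSE	table
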