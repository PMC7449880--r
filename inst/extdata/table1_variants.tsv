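sample_id	gene	hgvs_c	hgvs_p	tier	allele_fraction	confirmed	meth_tested	low_tumor	source
1105-001	BRCA1	c.3254_3255dupGA	p.(Leu1086Aspfs*2)	1	0.576	TRUE	TRUE	FALSE	table
1105-009	BRCA1	c.1961dupA	p.(Tyr655Valfs*18)	1	0.339	TRUE	TRUE	FALSE	table
1105-054	BRCA1	c.5266dupC	p.(Gln1756Profs*74)	1	0.584	TRUE	TRUE	FALSE	table
1105-110	BRCA1	c.1116G>A	p.(Trp372*)	1	0.801	TRUE	TRUE	FALSE	table
1105-113	BRCA1	c.182G>C	p.(Cys61Ser)	1	0.892	TRUE	TRUE	FALSE	table
1105-119	BRCA1	c.3967C>T	p.(Gln1323*)	1	0.933	TRUE	TRUE	FALSE	table
1105-123	BRCA1	c.5266dupC	p.(Gln1756Profs*74)	1	0.693	TRUE	TRUE	FALSE	table
1105-155	BRCA1	c.4327C>T	p.(Arg1443*)	1	0.461	TRUE	TRUE	FALSE	table
1105-192	BRCA1	c.68_69delAG	p.(Glu23Valfs*17)	1	0.763	TRUE	TRUE	FALSE	table
1105-193	BRCA1	c.3394_3406del	p.(Asn1132Leufs*19)	1	0.700	TRUE	TRUE	FALSE	table
1105-195	BRCA1	c.5059delG	p.(Val1687Leufs*3)	1	0.513	TRUE	TRUE	FALSE	table
1105-222	BRCA1	c.709G>T	p.(Glu237*)	1	0.512	TRUE	TRUE	FALSE	table
1105-227	BRCA1	c.5266dupC	p.(Gln1756Profs*74)	1	0.406	TRUE	TRUE	FALSE	table
1105-270	BRCA1	c.2891delG	p.(Gly964Aspfs*36)	1	0.584	TRUE	TRUE	FALSE	table
1105-273	BRCA1	c.4621G>T	p.(Glu1541*)	1	0.317	TRUE	TRUE	FALSE	table
1105-024	BRCA2	c.7615C>T	p.(Gln2539*)	1	0.111	FALSE	TRUE	FALSE	table
1105-078	BRCA2	c.8164dupA	p.(Thr2722Asnfs*8)	1	0.373	TRUE	TRUE	FALSE	table
1105-088	BRCA2	c.3170_3174del	p.(Lys1057Thrfs*8)	1	0.714	TRUE	TRUE	FALSE	table
1105-103	BRCA2	c.6591_6592delTG	p.(Glu2198Asnfs*4)	1	0.537	TRUE	TRUE	FALSE	table
1105-104	BRCA2	c.7954delG	p.(Val2652Cysfs*5)	1	0.385	TRUE	TRUE	FALSE	table
1105-137	BRCA2	c.7069_7070delCT	p.(Leu2357Valfs*2)	1	0.187	FALSE	TRUE	FALSE	table
1105-139	BRCA2	c.3587T>A	p.(Leu1196*)	1	0.733	TRUE	TRUE	FALSE	table
1105-152	BRCA2	c.3545_3546delTT	p.(Phe1182*)	1	0.340	TRUE	FALSE	TRUE	table
1105-200	BRCA2	c.7617+2T>G	NA	1	0.637	TRUE	TRUE	FALSE	table
1105-202	BRCA2	c.2588dupA	p.(Asn863Lysfs*18)	1	0.672	TRUE	TRUE	FALSE	table
1105-258	BRCA2	c.1054dupT	p.(Tyr352Leufs*6)	1	0.722	TRUE	TRUE	FALSE	table
1105-265	BRCA2	c.633dupC	p.(Arg212Glnfs*3)	1	0.452	TRUE	TRUE	TRUE	table
1105-159	BRCA1	c.5096G>A	p.(Arg1699Gln)	2	0.446	TRUE	TRUE	FALSE	table
1105-057	BRCA1	c.5095C>T	p.(Arg1699Trp)	2	0.442	TRUE	TRUE	FALSE	reconciled
1105-112	BRCA1	c.5207T>C	p.(Val1736Ala)	2	0.847	TRUE	TRUE	FALSE	reconciled
1105-162	BRCA1	c.212+3A>G	NA	2	0.967	TRUE	TRUE	FALSE	reconciled
1105-246	BRCA1	c.5074G>A	p.(Asp1692Asn)	2	0.728	TRUE	TRUE	FALSE	reconciled
1105-049	BRCA2	c.7958T>C	p.(Leu2653Pro)	2	0.994	TRUE	TRUE	FALSE	reconciled
1105-111	BRCA2	c.8167G>C	p.(Asp2723His)	2	0.696	TRUE	TRUE	FALSE	reconciled
1105-022	BRCA2	c.9338T>C	p.(Ile3113Thr)	2	0.756	TRUE	FALSE	FALSE	reconciled
1105-126	BRCA2	c.2716A>G	p.(Thr906Ala)	2	0.661	TRUE	FALSE	FALSE	reconciled
1105-024	BRCA1	c.2423_2481del	p.(Phe808Trpfs*3)	3	0.271	TRUE	TRUE	FALSE	reconciled
1105-119	BRCA2	c.9665G>T	p.(Cys3222Phe)	3	0.240	TRUE	TRUE	FALSE	reconciled
1105-103	BRCA2	c.9305C>T	p.(Ala3102Val)	3	0.431	TRUE	TRUE	FALSE	reconciled
1105-111	BRCA1	c.-62G>A	NA	3	0.571	TRUE	TRUE	FALSE	reconciled
1105-202	BRCA1	c.-86C>T	NA	3	0.833	TRUE	TRUE	FALSE	reconciled
1105-137	BRCA2	c.1094C>T	p.(Pro365Leu)	3	0.176	FALSE	TRUE	FALSE	reconciled
1105-182	BRCA1	c.5497G>A	p.(Val1833Met)	3	0.103	FALSE	FALSE	FALSE	table
1105-182	BRCA2	c.10112C>T	p.(Thr3371Ile)	3	0.105	FALSE	FALSE	FALSE	table
1105-059	BRCA1	c.4531C>T	p.(His1511Tyr)	3	0.122	FALSE	FALSE	FALSE	table
1105-120	BRCA2	c.44_45insATT	p.(Ile14_Phe15insLeu)	3	0.457	TRUE	FALSE	FALSE	table
1105-120	BRCA2	c.9502-12T>G	NA	3	0.825	TRUE	FALSE	FALSE	table
1105-120	BRCA2	c.41_67+9del	p.(?)	3	0.124	FALSE	FALSE	FALSE	table
1105-178	BRCA1	c.5416C>T	p.(Pro1806Ser)	3	0.147	FALSE	FALSE	FALSE	table
1105-220	BRCA2	c.5714A>T	p.(His1905Leu)	3	0.431	TRUE	FALSE	FALSE	table
1105-277	BRCA2	c.9698G>C	p.(Cys3233Ser)	3	0.477	TRUE	FALSE	FALSE	table
1105-183	BRCA1	c.2713C>G	p.(Gln905Glu)	3	0.239	TRUE	FALSE	FALSE	table
1105-041	BRCA1	c.4258C>T	p.(Gln1420*)	3	0.119	FALSE	FALSE	FALSE	table_unreconciled
1105-174	BRCA1	c.2212G>A	p.(Val738Ile)	3	0.102	FALSE	FALSE	FALSE	table_unreconciled
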