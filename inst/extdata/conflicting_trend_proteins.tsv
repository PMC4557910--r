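protein	protein_name	itraq_n_peptides	itraq_log2	itraq_p	lfq_n_peptides	lfq_log2	lfq_p
ARPC3	Actin-related protein 2/3 complex subunit 3	3	-0.25	0.04	2	0.37	0.47
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	7	-0.06	0.58	6	1.23	0.02
KHDRBS1	KH domain-containing, RNA-binding, signal transduction-associated protein 1	2	-0.25	0.10	4	0.63	0.02
USO1	General vesicular transport factor p115	4	-0.10	0.57	3	0.52	0.04
HP1BP3	Heterochromatin protein 1-binding protein 3	3	-0.30	0.04	6	0.72	0.17
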