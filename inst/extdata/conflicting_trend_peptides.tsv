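protein	protein_name	peptide	itraq_log2	lfq_log2
HP1BP3	Heterochromatin protein 1-binding protein 3	eASYSLIR	-0.24	0.03
HP1BP3	Heterochromatin protein 1-binding protein 3	mDAILTEAIk	-0.37	0.32
HP1BP3	Heterochromatin protein 1-binding protein 3	tIPSWATLSASQLAR	-0.30	0.41
HP1BP3	Heterochromatin protein 1-binding protein 3	SSAVDPEPQVK		1.31
HP1BP3	Heterochromatin protein 1-binding protein 3	LEDVLPLAFTR		0.24
HP1BP3	Heterochromatin protein 1-binding protein 3	GASGSFVVVQK		5.12
ARPC3	Actin-related protein 2/3 complex subunit 3	aYLQQLR	0.01	0.61
ARPC3	Actin-related protein 2/3 complex subunit 3	lIGNMALLPIR	-0.43	-0.06
ARPC3	Actin-related protein 2/3 complex subunit 3	lIGNmALLPIR	-0.34
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	sIVEEIEDLVAR	0.21	2.46
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	eDQVIQLMNAIFSk	-0.36
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	fELDTSER	0.15
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	nFESLSEAFSVASAAAVLSHNR	-0.12
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	qEIQHLFR	0.09
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	yHVPVVVVPEGSASDTHEQAILR	-0.38	0.62
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	LQVTNVLSQPLTQATVK		0.33
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	ISTEVGITNVDLSTVDKDQSIAPK		1.78
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	NPILWNVADVVIK		3.65
OST_SU2	Dolichyl-diphosphooligosaccharide--protein glycosyltransferase subunit 2	YIANTVELR	0.06	3.15
KHDRBS1	KH domain-containing, RNA-binding, signal transduction-associated protein 1	KDDEENYLDLFSHK		0.39
KHDRBS1	KH domain-containing, RNA-binding, signal transduction-associated protein 1	ILGPQGNTIK		0.55
KHDRBS1	KH domain-containing, RNA-binding, signal transduction-associated protein 1	DSLDPSFTHAMQLLTAEIEK		2.42
KHDRBS1	KH domain-containing, RNA-binding, signal transduction-associated protein 1	SGSMDPSGAHPSVR	0.06	0.68
KHDRBS1	KH domain-containing, RNA-binding, signal transduction-associated protein 1	qPPLPHR	-0.56
USO1	General vesicular transport factor p115	SSQTSGTNEQSSAIVSAR		0.27
USO1	General vesicular transport factor p115	SQLNSQSVEITK		0.25
USO1	General vesicular transport factor p115	NDGVLLLQALTR	-0.23	2.44
USO1	General vesicular transport factor p115	eQDLQLEELR	-0.47
USO1	General vesicular transport factor p115	qSEDLGSQFTEIFIk	0.31
USO1	General vesicular transport factor p115	vASSTLLDDRR	-0.00007
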