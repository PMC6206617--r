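assay_id	curator_positive	excluded	experiment_phrases	phenotype_phrases	quadrant
CHEMBL985321	1	0	avoidance test;scopolamine-induced;passive avoidance test		TP
CHEMBL1048342	1	0	forced swimming test	Immobility;swimming	TP
CHEMBL1212532	1	0	carrageenan-induced;carrageenan challenge	paw volume	TP
CHEMBL2149100	1	0	CCL4-induced;CCL4 challenge;CCL-induced	liver damage	TP
CHEMBL733509	1	0	Ip-implanted L1210 lymphoid leukemia	Leukemia;lymphoid leukemia	TP
CHEMBL843578	0	0			TN
CHEMBL825754	0	0			TN
CHEMBL851918	0	0			FP
CHEMBL1820580	0	0			FP
CHEMBL726986	0	0			FP
CHEMBL2020189	1	0	human A2780 cells xenografted		FN
CHEMBL786334	1	0	injection of kainic acid		FN
CHEMBL773481	1	0	induced by DiPr-5,6-ADTN	rectal temperature	FN
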