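assay_id	description	assay_type	bao_format	assay_organism_l2	target_organism_l2	src_id
CHEMBL985321	Antiamnesic activity in scopolamine-induced mouse assessed as latency time to enter dark room in retention session at 10 mg/kg, ip treated 20 min before training session by passive avoidance test	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL1048342	Antidepressant-like activity in NMRI mouse assessed as reduction in immobility time at 0.01 mg/kg, ip by forced swimming test	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL1212532	Antiinflammatory activity in Albino rat assessed as reduction of carrageenan-induced paw volume at 20 mg/kg, po administered 1 h before carrageenan challenge measured after 24 h (Rvb = 1.39 +/- 0.053 ml)	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL2149100	Hepatoprotective activity against CCL4-induced liver damage in ICR mouse assessed as reduction in CCL-induced iNOS mRNA expression at 100 mg/kg, ip dosed 30 min before and 2 h post CCL4 challenge and measured 24 h post CCL4 challenge by RT-PCR	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL733509	Median T/C calculated based on survivors at 300 mg/kg (318 umol) per day against Ip-implanted L1210 lymphoid leukemia mice	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL843578	Percent reduction was determined by using the ratio of mean of treated animal to that of control animal at a dose of 23.5 mg/kg	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL825754	Number of rats with greater than 100% GH increase over the controlgroup, there are five rats in both control and compound treated groups.	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL851918	Delta HR ratio measured as the ratio of delta HR(20 min)/delta HR (5 min)	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL1820580	Hypolipidemic activity in Swiss albino mouse assessed as decrease in plasma triglyceride level at 50 mg/kg, po administered daily for 8 days measured on day 9 by spectrophotometry relative to control	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL726986	Analgesic activity of compound (5.31 + diprenorphinen M) in mice after icv administration	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL2020189	Inhibition of PI3K-mediated AKT Ser473 phosphorylation in human A2780 cells xenografted in nu/nu mouse at 10 mg/kg, po after 10 h by immunoblotting	F	BAO_0000218	Mammalia		1
CHEMBL786334	Effect was expressed as mortality after injection of kainic acid (10 mg/kg) and the drug at the dose of 40 mg/Kg after 48 h	F	BAO_0000218	Mammalia	Mammalia	1
CHEMBL773481	Change in rectal temperature induced by DiPr-5,6-ADTN at a dose of 3.2 umol/kg of compound by subcutaneous administration	F	BAO_0000218	Mammalia	Mammalia	1
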