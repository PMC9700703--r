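set_name	role	code	is_prefix
cesarean	OUTCOME	O82	0
cesarean	OUTCOME	669.7	1
preterm	OUTCOME	O60.10	0
preterm	OUTCOME	O60.1	1
preterm	OUTCOME	644.2	1
stillbirth	OUTCOME	Z37.1	0
stillbirth	OUTCOME	Z37.3	0
stillbirth	OUTCOME	Z37.4	0
stillbirth	OUTCOME	656.4	1
infectious_disease	COVARIATE	B99.9	0
infectious_disease	COVARIATE	136	1
obesity	COVARIATE	E66.9	0
obesity	COVARIATE	E66	1
obesity	COVARIATE	278.0	1
cancer	COVARIATE	C80.1	0
cancer	COVARIATE	199	1
cardiovascular	COVARIATE	I51.9	0
cardiovascular	COVARIATE	429	1
circulatory	COVARIATE	I99.9	0
circulatory	COVARIATE	459	1
cerebrovascular	COVARIATE	I67.9	0
cerebrovascular	COVARIATE	437	1
respiratory	COVARIATE	J98.4	0
respiratory	COVARIATE	519	1
immune_disorders	COVARIATE	D84.9	0
immune_disorders	COVARIATE	279.9	1
organ_transplant	COVARIATE	Z94.0	0
organ_transplant	COVARIATE	Z94	1
obstetric_history	COVARIATE	Z87.51	0
obstetric_history	COVARIATE	Z87.5	1
maternal_care	COVARIATE	O26.9	0
maternal_care	COVARIATE	O26	1
maternal_care	COVARIATE	646	1
preeclampsia	COVARIATE	O14.1	0
preeclampsia	COVARIATE	O14	1
preeclampsia	COVARIATE	642.4	1
preeclampsia	COVARIATE	642.5	1
multiple_birth	COVARIATE	O30.9	0
multiple_birth	COVARIATE	O30	1
multiple_birth	COVARIATE	651	1
drug_allergies	COVARIATE	Z88.0	0
drug_allergies	COVARIATE	Z88	1
procedures	COVARIATE	Z98.89	0
procedures	COVARIATE	Z98	1
drug_resistance	COVARIATE	Z16.10	0
drug_resistance	COVARIATE	Z16	1
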