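name	fda_approved	approval_year	hiv_only_indication	pharmaceutical_or_biological	trial_includes_reproductive_age_females
oseltamivir	TRUE	1999	FALSE	TRUE	TRUE
hydroxychloroquine	TRUE	1955	FALSE	TRUE	TRUE
azithromycin	TRUE	1991	FALSE	TRUE	TRUE
amoxicillin	TRUE	1974	FALSE	TRUE	TRUE
famotidine	TRUE	1986	FALSE	TRUE	TRUE
methylprednisolone	TRUE	1957	FALSE	TRUE	TRUE
heparin	TRUE	1939	FALSE	TRUE	TRUE
enoxaparin	TRUE	1993	FALSE	TRUE	TRUE
aspirin	TRUE	1950	FALSE	TRUE	TRUE
ibuprofen	TRUE	1974	FALSE	TRUE	TRUE
remdesivir	TRUE	2020	FALSE	TRUE	TRUE
baricitinib	TRUE	2018	FALSE	TRUE	TRUE
experimental-ag7	FALSE	NA	FALSE	TRUE	TRUE
lopinavir	TRUE	2000	TRUE	TRUE	TRUE
dolutegravir	TRUE	2013	TRUE	TRUE	TRUE
convalescent-plasma	FALSE	NA	FALSE	FALSE	TRUE
vitamin-d-lifestyle-arm	TRUE	1950	FALSE	FALSE	TRUE
colchicine-male-only	TRUE	1961	FALSE	TRUE	FALSE
sarilumab-elderly-only	TRUE	2017	FALSE	TRUE	FALSE
tocilizumab	TRUE	2010	FALSE	TRUE	TRUE
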