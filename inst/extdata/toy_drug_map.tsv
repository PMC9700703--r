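raw_name	variable
oseltamivir	oseltamivir
Tamiflu	oseltamivir
hydroxychloroquine	hydroxychloroquine
Plaquenil	hydroxychloroquine
azithromycin	azithromycin
Zithromax	azithromycin
amoxicillin	amoxicillin
Amoxil	amoxicillin
famotidine	famotidine
Pepcid	famotidine
methylprednisolone	methylprednisolone
Medrol	methylprednisolone
heparin	heparin
enoxaparin	enoxaparin
Lovenox	enoxaparin
aspirin	aspirin
ibuprofen	ibuprofen
Advil	ibuprofen
Motrin	ibuprofen
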