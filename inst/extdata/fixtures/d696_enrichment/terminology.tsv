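scheme	code	label	parent_code	equivalents
icd	D50-D89	Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism
icd	D65-D69	Coagulation defects, purpura and other haemorrhagic conditions	D50-D89
icd	D69	Purpura and other haemorrhagic conditions	D65-D69
icd	D69.6	Thrombocytopenia, unspecified	D69
icd	D60	Acquired pure red cell aplasia	D50-D89
icd	D61	Other aplastic anaemias	D50-D89
sub	eltrombopag	Eltrombopag (synthetic demo substance)
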