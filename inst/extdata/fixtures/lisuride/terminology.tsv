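scheme	code	label	parent_code	equivalents
icd	E22	Hyperfunction of pituitary gland
icd	E22.0	Acromegaly and pituitary gigantism	E22
icd	E22.1	Hyperprolactinaemia	E22
icd	N91	Absent, scanty and rare menstruation
icd	N91.0	Primary amenorrhoea	N91
icd	N97	Female infertility
sub	lisuride	Lisuride
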