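scheme	code	label	parent_code	equivalents
icd	R00	Abnormalities of heart beat
icd	R00.0	Tachycardia, unspecified	R00
icd	R00.1	Bradycardia, unspecified	R00
icd	I47	Paroxysmal tachycardia
icd	I49	Other cardiac arrhythmias
icd	I49.5	Sick sinus syndrome	I49
icd	O68	Labour and delivery complicated by fetal stress
icd	O68.0	Labour and delivery complicated by fetal heart rate anomaly	O68
icd	O68.2	Labour and delivery complicated by fetal heart rate anomaly with meconium in amniotic fluid	O68
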