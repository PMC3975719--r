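scheme	code	label	parent_code	equivalents
icd	I48	Atrial fibrillation and flutter
icd	I48.2	Chronic atrial fibrillation	I48
icd	H81	Disorders of vestibular function
icd	H81.49	Vertigo of central origin, unspecified ear	H81
icd	I10	Essential (primary) hypertension
icd	E11	Type 2 diabetes mellitus
icd	E11.9	Type 2 diabetes mellitus without complications	E11
icd	N11	Chronic tubulo-interstitial nephritis
icd	N11.0	Nonobstructive reflux-associated chronic pyelonephritis	N11
atc	B01AC	Platelet aggregation inhibitors excl. heparin
atc	B01AC04	Clopidogrel	B01AC
atc	N07CA	Antivertigo preparations
atc	N07CA02	Cinnarizine	N07CA
atc	C09CA	Angiotensin II receptor blockers, plain
atc	C09CA06	Candesartan	C09CA
atc	C08CA	Dihydropyridine derivatives
atc	C08CA01	Amlodipine	C08CA
atc	A10BA	Biguanides
atc	A10BA02	Metformin	A10BA
atc	A10BH	Dipeptidyl peptidase 4 inhibitors
atc	A10BH01	Sitagliptin	A10BH
atc	J01MA	Fluoroquinolones
atc	J01MA02	Ciprofloxacin	J01MA
atc	M01AE	Propionic acid derivatives
atc	M01AE01	Ibuprofen	M01AE
sub	clopidogrel	Clopidogrel		atc:B01AC04
sub	cinnarizine	Cinnarizine		atc:N07CA02
sub	candesartan	Candesartan		atc:C09CA06
sub	amlodipine	Amlodipine		atc:C08CA01
sub	metformin	Metformin		atc:A10BA02
sub	sitagliptin	Sitagliptin		atc:A10BH01
sub	ciprofloxacin	Ciprofloxacin		atc:J01MA02
sub	ibuprofen	Ibuprofen		atc:M01AE01
sub	fosfomycin	Fosfomycin
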