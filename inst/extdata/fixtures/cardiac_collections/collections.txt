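# Expert-defined condition groups for cardiac rhythm abnormalities.
# cardiac-rhythm-abnormalities nests two other collections.
cardiac-rhythm-abnormalities = cc:bradycardia | icd:R00 | cc:tachycardia | icd:O68.0 | icd:O68.2
bradycardia = icd:I49.5 | icd:R00.1 | icd:O68.0
tachycardia = icd:R00.0 | icd:I49.5 | icd:I47 | icd:O68.0
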