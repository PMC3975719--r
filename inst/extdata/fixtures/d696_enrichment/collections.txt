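# Bone-marrow deficiency conditions. D69.6 membership is the documented
# example; the remaining members are synthetic but clinically plausible.
deficiency-bone-marrow = icd:D60 | icd:D61 | icd:D69.6
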