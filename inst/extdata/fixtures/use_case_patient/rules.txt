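# version: use-case-demo
# Synthetic demonstration rule base around the pyelonephritis encounter.
# Indications for treating the new diagnosis:
ciprofloxacin = icd:N11.0 | icd:N11
fosfomycin = icd:N11.0, ageGroup=adult or elder
ibuprofen = icd:N11.0
# Drug-drug interaction: NSAID on top of an antithrombotic agent.
!ibuprofen = cc:antithrombotic-agents
# Drug-disease contraindication: biguanide caution in renal infection.
!metformin = icd:N11.0
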