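{
  "id": "thrombocytopenia-patient",
  "data": ["icd:D69.6"],
  "age_group": "adult",
  "sex_group": "male"
}
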