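{
  "id": "hyperprolactinaemia-patient",
  "data": ["icd:E22.1", "icd:N97"],
  "age_group": "adult",
  "sex_group": "female"
}
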