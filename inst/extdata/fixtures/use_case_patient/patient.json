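{
  "id": "use-case-elder",
  "data": ["icd:I48.2", "icd:H81.49", "icd:I10", "icd:E11.9", "icd:N11.0",
           "atc:B01AC04", "atc:N07CA02", "atc:C09CA06", "atc:C08CA01",
           "atc:A10BA02", "atc:A10BH01"],
  "age_group": "elder",
  "sex_group": "male"
}
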