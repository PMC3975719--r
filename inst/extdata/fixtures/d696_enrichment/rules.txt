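# version: d696-demo
# Synthetic demo rule: a substance indicated for bone-marrow deficiency
# conditions, premised on the custom collection rather than individual codes.
eltrombopag = cc:deficiency-bone-marrow
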