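# Synthetic condition group used by the demo contraindication rule:
# antithrombotic agents the elder patient is already taking.
antithrombotic-agents = atc:B01AC04 | sub:clopidogrel
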