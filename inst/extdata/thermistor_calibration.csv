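temperature_C,resistance_kohm
4,274
22,114
30,81
37,60
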