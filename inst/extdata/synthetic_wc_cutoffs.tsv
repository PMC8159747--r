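sex	age_years	cutoff
M	2	50.1
M	4	54.0
M	6	58.3
M	8	63.5
M	10	69.0
M	12	74.0
M	14	78.0
M	16	81.0
F	2	49.5
F	4	53.2
F	6	57.2
F	8	62.8
F	10	68.0
F	12	72.5
F	14	76.0
F	16	79.0
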