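sex	age_years	cutoff
M	2	18.4
M	4	19.3
M	6	19.76
M	8	21.6
M	10	24.0
M	12	26.0
M	14	27.6
M	16	28.9
F	2	18.0
F	4	19.1
F	6	19.62
F	8	21.6
F	10	24.1
F	12	26.7
F	14	27.8
F	16	28.6
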