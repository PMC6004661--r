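stratum	level	cases	total
sex	male	363	23669
sex	female	291	15218
age	0-9	0	40
age	10-19	1	86
age	20-29	3	215
age	30-39	11	748
age	40-49	39	1990
age	50-59	85	5115
age	60-69	204	11399
age	70-79	213	13178
age	80-89	87	5568
age	90-99	11	548
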