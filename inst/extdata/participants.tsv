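subject	sex	age	bmi	daily_energy_kcal
1	F	22	23.4	1940
2	M	30	28.9	3267
3	M	26	26.9	2983
4	M	28	22.4	2884
5	F	23	32.2	2116
6	F	19	18.9	2221
7	M	29	27.1	3118
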