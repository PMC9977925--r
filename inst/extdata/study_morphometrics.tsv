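tag	sex	tissue	size_code	sample_id	weight_g	total_length_cm	standard_length_cm
F1-5mts-1	female	Liver	B	BL1	512	29	24
F1-5mts-6	female	Liver	B	BL2	634	30.2	25.5
F1-5mts-8	female	Liver	B	BL3	587	29.5	24.5
F1-5mts-11	female	Liver	B	BL4	584	28.5	23.5
F1-5mts-12	female	Liver	B	BL5	556	29	23.7
F1-5mts-3	female	Liver	S	SL1	191	21.4	17.5
F1-5mts-7	female	Liver	S	SL2	113	17.8	14
F1-5mts-9	female	Liver	S	SL3	138	18.6	15
F1-5mts-13	female	Liver	S	SL4	192	21.6	17.7
F1-5mts-14	female	Liver	S	SL5	129	19.3	15.7
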