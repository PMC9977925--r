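group	sample_id	sra_accession	manipulation	raw_reads	total_5hmc	unique_5hmc
control	C1a	SRS7585929	RRHP - second MspI digestion omitted	45994060	22618039	611908
control	C1b	SRS7585930	RRHP - second MspI digestion omitted	34339125	16324747	556289
large	BL1	SRS7412736	RRHP protocol	29951172	4702129	411812
large	BL2	SRS7412737	RRHP protocol	64951163	15790930	517979
large	BL3	SRS7412738	RRHP protocol	46520470	17040820	478241
large	BL4	SRS7412739	RRHP protocol	65123992	27719382	544846
large	BL5	SRS7412740	RRHP protocol	56155408	18040871	534659
small	SL1	SRS7412741	RRHP protocol	21105349	3441132	371621
small	SL2	SRS7412742	RRHP protocol	27287570	7637187	383449
small	SL3	SRS7412743	RRHP protocol	7105158	2466658	279178
small	SL4	SRS7412744	RRHP protocol	24225784	6106860	389376
small	SL5	SRS7412745	RRHP protocol	12690867	3898492	318951
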