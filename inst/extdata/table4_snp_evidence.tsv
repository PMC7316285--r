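gene_symbol	chromosome	start	end	snp_name	distance_mb	trait_code
EEPD1	4	61354648	61476979	Hapmap42645-BTA-70875	1.84	CC
MYH10	19	28680825	28800880	UA-IFASA-9813	3.92	CW
MYH10	19	28680825	28800880	ARS-BFGL-NGS-88422	0.82	CC
CYP2R1	15	38420926	38445583	ARS-BFGL-NGS-117790	2.12	CC
GADL1	22	5258463	5452369	ARS-BFGL-NGS-27027	0.06	CC
MYH1	19	30110728	30134757	UA-IFASA-9813	2.58	CW
MYH1	19	30110728	30134757	ARS-BFGL-NGS-88422	2.25	CC
SHISA3	6	62877287	62880849	BTA-76543-no-rs	1.13	IMFP
MYH4	19	30080604	30103436	UA-IFASA-9813	2.61	CW
MYH4	19	30080604	30103436	ARS-BFGL-NGS-88422	2.22	CC
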