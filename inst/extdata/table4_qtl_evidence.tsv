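gene_symbol	chromosome	start	end	qtl_id	distance_cm	trait_code
EEPD1	4	61354648	61476979	20355	0.6	CW
EEPD1	4	61354648	61476979	20368	0.6	FT12R
MYH10	19	28680825	28800880	22873	-22.3	IMF
MYH10	19	28680825	28800880	22872	-2.6	IMF
CYP2R1	15	38420926	38445583	24706	-6.7	LDMA
GADL1	22	5258463	5452369	37164	-2.0	LMY
MYH1	19	30110728	30134757	22873	-19.9	IMF
SHISA3	6	62877287	62880849	20764	-0.8	SF
MYH4	19	30080604	30103436	22873	-19.9	IMF
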