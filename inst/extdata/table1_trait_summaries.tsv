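trait	group	mean	se	n	sem_printed	p_printed
initial_weight_kg	bull	275.90	5.62	10	6.458	0.306
initial_weight_kg	steer	269.10	3.18	10	6.458	0.306
carcass_weight_kg	bull	455.40	7.82	10	9.784	0.047
carcass_weight_kg	steer	434.50	5.88	10	9.784	0.047
rib_eye_area_cm2	bull	91.00	2.74	10	4.012	0.002
rib_eye_area_cm2	steer	76.10	2.93	10	4.012	0.002
marbling_score	bull	2.30	0.15	10	0.269	0.008
marbling_score	steer	3.10	0.22	10	0.269	0.008
shear_force	bull	3.62	0.56	10	0.760	0.949
shear_force	steer	3.57	0.51	10	0.760	0.949
water_pct	bull	72.67	1.14	10	1.866	0.024
water_pct	steer	67.49	1.48	10	1.866	0.024
imf_pct	bull	7.04	0.69	10	2.02	0.048
imf_pct	steer	12.29	1.90	10	2.02	0.048
protein_pct	bull	20.59	0.40	10	0.573	0.102
protein_pct	steer	19.53	0.41	10	0.573	0.102
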