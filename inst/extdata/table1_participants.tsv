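variable	group	timepoint	mean	sd
female_sex_pct	high	baseline	64.5	NA
female_sex_pct	low	baseline	65.7	NA
age_y	high	baseline	42.2	6.7
age_y	low	baseline	42.5	5.7
weight_loss_pct	high	2m	12.3	2.9
weight_loss_pct	high	8m	15.4	4.6
weight_loss_pct	low	2m	10.0	1.9
weight_loss_pct	low	8m	5.8	3.4
weight_kg	high	baseline	100.4	18.3
weight_kg	high	2m	87.9	15.9
weight_kg	high	8m	84.8	15.8
weight_kg	low	baseline	97.7	16.7
weight_kg	low	2m	88.0	15.1
weight_kg	low	8m	92.0	15.7
bmi_kg_m2	high	baseline	34.6	4.8
bmi_kg_m2	high	2m	30.3	4.3
bmi_kg_m2	high	8m	29.2	4.2
bmi_kg_m2	low	baseline	34.0	4.4
bmi_kg_m2	low	2m	30.6	4.1
bmi_kg_m2	low	8m	32.0	4.1
cholesterol_mmol_l	high	baseline	4.8	0.9
cholesterol_mmol_l	low	baseline	4.9	1.1
ldl_mmol_l	high	baseline	3.0	0.8
ldl_mmol_l	low	baseline	3.1	0.9
hdl_mmol_l	high	baseline	1.2	0.3
hdl_mmol_l	low	baseline	1.3	0.3
tag_mmol_l	high	baseline	1.4	0.6
tag_mmol_l	low	baseline	1.4	0.7
nefa_umol_l	high	baseline	680	294
nefa_umol_l	low	baseline	640	281
glucose_mmol_l	high	baseline	5.1	0.6
glucose_mmol_l	low	baseline	5.1	0.6
insulin_mu_l	high	baseline	12.6	18.1
insulin_mu_l	low	baseline	10.9	6.5
homa_ir	high	baseline	3.4	5.0
homa_ir	low	baseline	2.9	1.9
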