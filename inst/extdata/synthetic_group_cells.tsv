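intensity	variant	gene	ethnicity	ma	n	sbp_mean	sbp_sd	dbp_mean	dbp_sd
VIGOROUS	rs1055086	ACE	AF	0	11	3.7	10.1	2.6	5.5
VIGOROUS	rs1055086	ACE	AF	1	3	-20.8	18.2	-13.7	8.4
VIGOROUS	rs74662294	AGTR1	AF	0	13	0.6	13.7	0.6	7.6
VIGOROUS	rs74662294	AGTR1	AF	1	1	-30.0	NA	-19.7	NA
VIGOROUS	rs4546	CYP11B2	AF	0	8	2.3	10.5	2.8	5.2
VIGOROUS	rs4546	CYP11B2	AF	1	5	-1.9	18.9	-3.0	10.0
VIGOROUS	rs4546	CYP11B2	AF	2	1	-29.8	NA	-19.7	NA
VIGOROUS	rs4537	CYP11B2	AF	0	13	0.6	13.7	0.6	7.8
VIGOROUS	rs4537	CYP11B2	AF	1	1	-29.8	NA	-19.7	NA
VIGOROUS	rs16843169	ADD1	AF	0	12	1.4	14.0	0.1	7.7
VIGOROUS	rs16843169	ADD1	AF	1	2	-19.0	15.2	-6.6	18.5
VIGOROUS	rs6833874	ADD1	AF	0	10	4.1	10.6	2.6	6.0
VIGOROUS	rs6833874	ADD1	AF	1	4	-15.5	18.4	-9.8	10.4
MODERATE	rs3730036	ACE	AF	0	13	-4.7	7.3	-3.5	6.0
MODERATE	rs3730036	ACE	AF	1	1	16.1	NA	3.9	NA
MODERATE	rs6432	CYP11B2	AF	0	13	-4.7	7.3	-3.5	6.0
MODERATE	rs6432	CYP11B2	AF	1	1	16.1	NA	3.9	NA
MODERATE	rs3802228	CYP11B2	AF	0	11	-5.5	7.3	-3.9	6.4
MODERATE	rs3802228	CYP11B2	AF	1	2	-0.5	8.3	-1.5	2.7
MODERATE	rs3802228	CYP11B2	AF	2	1	16.8	NA	3.9	NA
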