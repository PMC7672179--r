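patient_id	method	rank	candidate_id	immunogenic	tpm
P01	TruNeo	1	E01	1	48.2
P01	TruNeo	4	E02	1	12.5
P02	TruNeo	2	E03	1	33.0
P02	TruNeo	5	E04	1	7.8
P03	TruNeo	1	E05	1	91.4
P03	TruNeo	3	E06	1	22.1
P04	TruNeo	7	E07	1	15.6
P04	TruNeo	9	E08	1	5.2
P05	TruNeo	6	E09	1	64.9
P05	TruNeo	8	E10	1	18.3
P06	TruNeo	12	E11	1	9.7
P06	TruNeo	15	E12	1	41.0
P07	TruNeo	18	E13	1	27.5
P08	TruNeo	25	E14	1	3.4
P09	TruNeo	40	E15	1	55.8
P10	TruNeo	33	E16	1	14.2
P11	TruNeo	27	E17	1	70.3
P12	TruNeo	55	E18	1	6.1
P13	TruNeo	22	E19	1	36.9
P01	TruNeo	2	D01	0	1.2
P01	TruNeo	3	D02	0	0.8
P02	TruNeo	1	D03	0	19.4
P03	TruNeo	2	D04	0	1.6
P01	MHCflurry	2	E01	1	48.2
P01	MHCflurry	13	E02	1	12.5
P02	MHCflurry	3	E03	1	33.0
P02	MHCflurry	16	E04	1	7.8
P03	MHCflurry	4	E05	1	91.4
P03	MHCflurry	11	E06	1	22.1
P04	MHCflurry	1	E07	1	15.6
P04	MHCflurry	19	E08	1	5.2
P05	MHCflurry	23	E09	1	64.9
P05	MHCflurry	31	E10	1	18.3
P06	MHCflurry	26	E11	1	9.7
P06	MHCflurry	44	E12	1	41.0
P07	MHCflurry	35	E13	1	27.5
P08	MHCflurry	28	E14	1	3.4
P09	MHCflurry	52	E15	1	55.8
P10	MHCflurry	61	E16	1	14.2
P11	MHCflurry	38	E17	1	70.3
P12	MHCflurry	47	E18	1	6.1
P13	MHCflurry	29	E19	1	36.9
P01	MHCflurry	1	D01	0	1.2
P02	MHCflurry	2	D03	0	19.4
P03	MHCflurry	1	D04	0	1.6
P01	NetMHCpan4	3	E01	1	48.2
P01	NetMHCpan4	8	E02	1	12.5
P02	NetMHCpan4	14	E03	1	33.0
P02	NetMHCpan4	1	E04	1	7.8
P03	NetMHCpan4	12	E05	1	91.4
P03	NetMHCpan4	5	E06	1	22.1
P04	NetMHCpan4	17	E07	1	15.6
P04	NetMHCpan4	24	E08	1	5.2
P05	NetMHCpan4	2	E09	1	64.9
P05	NetMHCpan4	11	E10	1	18.3
P06	NetMHCpan4	32	E11	1	9.7
P06	NetMHCpan4	21	E12	1	41.0
P07	NetMHCpan4	20	E13	1	27.5
P08	NetMHCpan4	45	E14	1	3.4
P09	NetMHCpan4	27	E15	1	55.8
P10	NetMHCpan4	39	E16	1	14.2
P11	NetMHCpan4	58	E17	1	70.3
P12	NetMHCpan4	26	E18	1	6.1
P13	NetMHCpan4	33	E19	1	36.9
P01	NetMHCpan4	1	D01	0	1.2
P02	NetMHCpan4	2	D03	0	19.4
P03	NetMHCpan4	1	D04	0	1.6
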