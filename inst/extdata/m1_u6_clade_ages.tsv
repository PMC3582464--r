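clade	n	rho_syn	age_syn	age_syn_pm	rho_full	age_full	ci_low	ci_high
M1	100	3.6	28900	7600	9.45	26100	17900	34700
M1a	78	2.62	20900	4900	7.76	21200	15000	27600
M1a1	42	2.02	16200	3300	5.43	14600	10400	18800
M1a2	15	1.93	15400	5700	6.4	17300	9500	25500
M1a3	10	1.8	14400	6100	4.4	11700	6700	16900
M1b	22	2.55	20300	5700	7.36	20000	12400	28000
M1b1	9	1.33	10700	5300	3.44	9800	3800	14500
M1b2	13	2	16000	4400	4.62	12300	8000	16800
U6	139	4.11	32800	7000	12.27	34600	24100	45500
U6a	104	3.74	29900	4600	9.16	25300	20100	30600
U6a1	22	2.73	21800	6400	6.59	17900	10700	25200
U6a2	12	1.58	12700	4900	7	19000	11600	26700
U6a3	22	2.36	18800	5100	6.86	18600	12400	25000
U6a7	27	4.7	37600	12800	10.4	27900	15600	40800
U6b	21	1.19	9500	2800	5	13400	7500	19500
U6c	5	1	8000	5300	4.2	11200	4700	17900
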