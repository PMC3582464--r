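population	region	n	U6	U6a	U6b	M1	M1a	M1b
Guinea-Bissau	WA	372	8	8	0	4	0	4
Morocco	NWA	530	40	30	4	23	11	12
Algeria	NWA	127	13	10	1	2	1	1
Tunisia	NWA	516	23	16	6	17	11	6
Libya	NEA	101	5	5	0	1	0	1
Egypt	NEA	193	5	5	0	14	13	1
Ethiopia	EA	270	8	8	0	45	45	0
Lebanon	NE	171	4	4	0	2	2	0
Saudi Arabia	NE	205	3	3	0	8	6	2
Kuwait	NE	202	0	0	0	1	1	0
Yemen	NE	115	0	0	0	1	1	0
Jordan	NE	210	2	2	0	4	4	0
Iran	NE	436	1	1	0	1	0	1
Oman	NE	80	2	1	1	0	0	0
Cyprus	NE	180	1	0	1	4	4	0
Crete	EUR	193	0	0	0	2	2	0
Sicily	EUR	552	4	4	0	0	0	0
Russia	EUR	678	0	0	0	1	1	0
Abkhaz	Caucasus	146	0	0	0	1	1	0
Abazas	Caucasus	93	0	0	0	3	3	0
Karachays	Caucasus	106	0	0	0	1	1	0
Kumyks	Caucasus	112	0	0	0	1	1	0
Cherkes	Caucasus	124	0	0	0	4	4	0
Ossetians	Caucasus	162	0	0	0	4	4	0
Kabardins	Caucasus	142	0	0	0	1	1	0
Chechens	Caucasus	176	0	0	0	2	2	0
Nogays	Caucasus	81	0	0	0	1	1	0
Armenians	Caucasus	249	1	1	0	0	0	0
Georgians	Caucasus	402	0	0	0	1	1	0
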