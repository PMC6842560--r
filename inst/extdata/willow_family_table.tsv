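name	sequence_id	class	chromosome	orthologues_sp1	orthologues_sp2	orthologues_sp3	length_aa	mw_kda	pi	introns
SsMADS1	willow_GLEAN_10012476	MIKCc	chr01	101	20	50	209	24.00	8.53	6
SsMADS2	willow_GLEAN_10012473	MIKCc	chr01	97	6	6,17	232	27.06	9.1	7
SsMADS3	willow_GLEAN_10014137	Mγ	chr01	46	–	–	401	43.52	7.05	0
SsMADS4	willow_GLEAN_10007397	Mα	chr01	47,48	–	–	530	60.23	6.67	8
SsMADS5	willow_GLEAN_10007399	Mα	chr01	47,48	–	–	212	24.34	6.22	0
SsMADS6	willow_GLEAN_10011253	Mβ	chr01	90	–	–	595	67.62	9.16	7
SsMADS7	willow_GLEAN_10022499	MIKCc	chr02	69	APETALA3	16	220	25.64	9.15	6
SsMADS8	willow_GLEAN_10020801	MIKCc	chr02	64	PISTILLATA	16	829	92.12	6.57	7
SsMADS9	willow_GLEAN_10020993	MIKCc	chr02	68	24	47	222	24.91	8.33	6
SsMADS10	willow_GLEAN_10021024	MIKCc	chr02	66	16	57	217	24.78	9.59	5
SsMADS11	willow_GLEAN_10011768	MIKCc	chr02	71	14	50	165	18.94	9.35	4
SsMADS12	willow_GLEAN_10020216	Mβ	chr02	67,102	–	–	405	45.69	7.57	0
SsMADS13	willow_GLEAN_10025520	MIKCc	chr03	94	14	50	287	32.58	10.07	5
SsMADS14	willow_GLEAN_10008017	MIKCc	chr03	95	2,9	7∕45, 8∕24	245	27.96	8.58	7
SsMADS15	willow_GLEAN_10008015	MIKCc	chr03	35,26	–	6,17	263	29.40	9.31	4
SsMADS16	willow_GLEAN_10008014	MIKCc	chr03	35,26	–	6,17	218	24.65	7.83	6
SsMADS17	willow_GLEAN_10017246	MIKCc	chr04	25	AGAMOUS	58	350	39.19	9.3	8
SsMADS18	willow_GLEAN_10011967	Mα	chr04	21	–	–	194	21.74	9.08	0
SsMADS19	willow_GLEAN_10011966	Mα	chr04	27	29	–	178	20.10	9.96	0
SsMADS20	willow_GLEAN_10009082	MIKCc	chr05	53	–	29	219	25.34	8.54	4
SsMADS21	willow_GLEAN_10027002	MIKCc	chr06	43	15	57	250	28.08	8.65	7
SsMADS22	willow_GLEAN_10025994	Mγ	chr06	44	48	–	469	51.05	5.84	0
SsMADS23	willow_GLEAN_10026418	Mα	chr06	12,42	–	–	374	40.67	4.44	0
SsMADS24	willow_GLEAN_10012682	MIKCc	chr07	49	APETALA3	16	229	26.62	8.84	6
SsMADS25	willow_GLEAN_10007501	MIKCc	chr07	53	90	29	233	27.19	7.71	5
SsMADS26	willow_GLEAN_10007031	MIKC*	chr07	52	104	63	364	41.19	5.61	10
SsMADS27	willow_GLEAN_10014009	Mα	chr07	6	43	–	254	28.19	9.17	1
SsMADS28	willow_GLEAN_10014039	MIKC*	chr07	51	–	–	169	19.01	9.3	4
SsMADS29	willow_GLEAN_10024615	Mβ	chr08	84	–	–	202	22.90	6	0
SsMADS30	willow_GLEAN_10024753	Mα	chr08	17	–	–	197	22.70	9.36	0
SsMADS31	willow_GLEAN_10025082	MIKC*	chr08	85	30	68	357	39.79	6.95	9
SsMADS32	willow_GLEAN_10025158	MIKCc	chr08	87,95	2,9	7∕45, 8∕24	241	27.62	5.65	7
SsMADS33	willow_GLEAN_10025159	MIKCc	chr08	86	7	15	212	24.53	8.48	5
SsMADS34	willow_GLEAN_10008129	MIKC*	chr09	57	–	–	80	9.23	10.33	1
SsMADS35	willow_GLEAN_10022978	Mα	chr09	19	–	–	205	23.07	5.29	0
SsMADS36	willow_GLEAN_10023049	MIKCc	chr09	15	15	29	259	29.39	8.81	7
SsMADS37	willow_GLEAN_10024397	MIKCc	chr09	89,66	44	57,61	263	30.14	9.39	6
SsMADS38	willow_GLEAN_10024365	Mα	chr09	18	43	–	416	46.75	9.62	2
SsMADS39	willow_GLEAN_10021705	Mα	chr10	29,7	–	–	203	23.09	5.25	0
SsMADS40	willow_GLEAN_10013611	MIKC*	chr10	85	30	68	894	98.51	6.62	13
SsMADS41	willow_GLEAN_10019310	Mβ	chr10	2	–	–	342	37.50	8.32	1
SsMADS42	willow_GLEAN_10004380	Mβ	chr10	1	–	–	201	22.46	5.02	0
SsMADS43	willow_GLEAN_10005930	MIKCc	chr11	41	AGAMOUS	3	227	25.81	9.62	5
SsMADS44	willow_GLEAN_10013792	MIKCc	chr12	103	–	34	135	15.72	9.47	3
SsMADS45	willow_GLEAN_10006110	MIKCc	chr13	103	–	34	232	26.73	8.84	5
SsMADS46	willow_GLEAN_10016051	MIKCc	chr14	82	6	7,16	218	25.40	9.85	6
SsMADS47	willow_GLEAN_10016052	MIKCc	chr14	83	20	50	218	25.38	9.55	6
SsMADS48	willow_GLEAN_10004716	Mβ	chr15	60	–	–	220	25.26	6.85	0
SsMADS49	willow_GLEAN_10009701	MIKCc	chr15	–	20	50	266	31.05	8.98	7
SsMADS50	willow_GLEAN_10023443	MIKCc	chr16	95	2,9	7∕45, 8∕24	267	30.54	6.26	8
SsMADS51	willow_GLEAN_10003749	MIKCc	chr16	94	14	50	255	28.99	9.34	7
SsMADS52	willow_GLEAN_10002958	Mβ	chr16	20	–	–	265	30.53	5.37	0
SsMADS53	willow_GLEAN_10003926	MIKCc	chr17	23	29	7∕45, 8∕24	245	28.17	8.27	7
SsMADS54	willow_GLEAN_10003927	MIKCc	chr17	14,26	8	14,15	238	27.54	9.18	6
SsMADS55	willow_GLEAN_10006611	Mα	chr18	–	–	–	310	33.64	4.74	0
SsMADS56	willow_GLEAN_10013302	MIKCc	chr19	72,31	12	26	321	36.31	8.47	4
SsMADS57	willow_GLEAN_10001835	MIKC*	N/A	45	–	–	82	9.51	9.9	1
SsMADS58	willow_GLEAN_10001302	MIKCc	N/A	31	12	26	156	17.88	9.1	3
SsMADS59	willow_GLEAN_10001292	Mγ	N/A	34	80	–	235	26.81	9.27	0
SsMADS60	willow_GLEAN_10000968	Mγ	N/A	–	–	–	158	18.14	5.99	0
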