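sample_id	taxon01	taxon02	taxon03	taxon04	taxon05	taxon06	taxon07	taxon08	taxon09	taxon10	taxon11	taxon12	taxon13	taxon14	taxon15	taxon16	taxon17	taxon18	taxon19	taxon20	taxon21	taxon22	taxon23	taxon24	taxon25	taxon26	taxon27	taxon28	taxon29	taxon30
S001	765	151	0	0	480	24	234	44	91	109	537	830	72	43	30	314	37	30	4	869	133	0	527	778	904	91	206	21	13	95
S002	224	21	44	18	43	24	0	12	423	0	0	521	8	28	25	56	10	0	2	303	20	9	135	704	106	32	128	4	71	25
S003	180	57	57	73	35	220	66	0	0	24	375	2193	3	33	14	67	88	0	0	127	5	4	22	156	445	2	77	2	56	58
S004	519	43	91	92	110	286	92	108	2000	39	119	901	3	45	29	710	19	9	3	143	25	7	10	120	928	20	6	9	50	75
S005	0	44	193	134	90	165	0	152	280	41	0	837	51	212	95	106	216	15	37	128	122	90	279	242	2181	39	63	73	180	216
S006	853	0	119	291	300	24	4075	13	218	108	384	1934	78	6	0	352	0	9	0	1192	94	2	582	2377	1596	53	0	9	140	252
S007	662	80	190	265	453	46	921	210	238	0	396	2940	69	0	106	95	69	2	8	117	173	70	62	0	652	0	647	3	0	251
S008	727	28	172	554	313	68	465	49	121	350	2483	1501	15	107	112	156	71	12	0	1729	14	186	0	146	0	226	0	101	421	24
S009	326	53	222	185	0	93	994	12	245	39	56	1189	9	151	52	229	202	5	5	295	11	5	97	339	345	8	97	3	22	61
S010	799	136	615	893	452	99	3480	27	0	235	178	2089	17	73	61	764	108	10	23	6793	113	0	718	614	449	78	0	57	96	455
S011	884	42	303	0	335	95	9502	0	1652	0	2790	354	77	0	69	0	6	25	5	0	195	4	57	1910	531	9	2762	44	181	751
S012	810	46	69	0	617	28	92	1013	766	87	0	3417	13	312	65	270	28	9	24	253	219	196	191	221	604	30	572	2	140	55
S013	747	313	334	1189	1296	59	254	234	1089	231	762	1284	16	48	24	323	249	42	9	1309	37	14	213	0	1967	78	67	14	285	125
S014	483	45	85	47	136	60	815	39	618	63	426	467	67	49	522	2221	148	2	10	191	259	48	48	0	0	132	123	49	46	71
S015	174	55	37	173	80	275	0	0	2198	335	139	5087	44	20	226	525	289	24	30	6073	870	55	148	388	3833	67	157	92	316	178
S016	350	71	168	360	361	8	0	148	399	24	847	1309	53	74	0	1683	15	10	10	577	135	0	262	0	265	45	78	21	267	16
S017	1056	132	581	388	398	311	0	0	1078	475	0	738	14	418	286	617	540	46	37	122	106	8	595	395	144	113	120	109	213	846
S018	1525	111	296	175	657	23	623	201	3216	237	1006	1150	0	19	98	303	28	14	0	492	53	15	8	317	159	26	159	90	316	25
S019	835	86	465	564	313	323	681	65	150	157	93	0	4	12	63	59	13	4	13	359	115	6	90	1402	201	60	161	23	677	162
S020	587	158	125	524	63	115	2331	184	2100	61	564	3392	1	229	20	135	1164	8	7	1140	61	0	76	32	1222	38	66	19	694	75
S021	211	60	92	102	57	478	1105	158	642	17	0	1683	14	32	375	31	35	0	10	1108	18	14	73	1521	1947	36	271	5	51	188
S022	803	209	315	191	369	50	6840	2	263	186	15	377	19	21	13	82	120	0	16	0	15	2	0	176	906	0	40	25	201	52
S023	1573	331	680	729	1191	12	2260	67	2965	72	2254	0	21	128	42	229	366	3	2	409	451	44	38	392	945	57	72	2	196	16
S024	125	36	59	70	28	27	284	89	1881	50	0	2201	14	954	32	766	32	15	11	193	39	0	111	671	1369	279	408	6	861	47
S025	565	23	209	96	120	151	1038	0	324	70	100	1254	17	524	10	173	26	3	38	109	268	7	147	97	1620	179	16	48	119	208
S026	211	31	252	248	237	0	229	0	1372	0	63	1724	8	49	60	196	42	12	5	443	154	42	99	642	1876	47	29	5	117	163
S027	248	35	81	142	125	135	0	278	377	97	4424	748	72	38	0	352	30	18	34	1085	4	27	0	331	0	50	13	7	185	158
S028	2185	147	163	149	195	115	1022	332	964	364	2595	0	121	209	337	166	183	17	3	3794	95	4	198	1399	961	110	334	25	120	93
S029	2105	109	23	487	56	12	536	89	616	47	647	1144	10	0	17	0	0	0	0	382	55	29	84	236	692	0	1348	1	529	517
S030	0	172	31	44	119	75	35	0	116	14	1251	1809	9	257	23	330	193	0	15	171	20	24	35	99	132	148	92	43	51	42
S031	560	37	239	540	205	63	1117	42	1017	127	3743	160	54	0	137	0	75	8	29	426	106	22	0	574	512	36	120	5	321	23
S032	0	30	0	153	78	192	0	0	1460	918	653	3897	149	234	116	231	0	16	13	131	297	12	129	147	5154	369	162	18	77	95
S033	678	45	404	633	115	155	274	232	0	30	1026	881	95	29	34	169	205	12	25	261	19	36	95	0	821	293	54	17	852	29
S034	0	74	0	440	429	130	1003	66	0	243	443	1100	28	207	179	3507	0	15	6	1228	63	29	295	0	657	64	111	86	0	66
S035	1279	233	354	94	208	11	382	75	1641	1264	786	950	98	274	181	168	222	18	11	3945	1129	16	185	138	611	73	108	139	110	120
S036	457	21	73	143	14	203	78	41	1568	73	320	265	3	18	84	227	45	7	6	105	74	4	311	12	1566	26	167	4	81	41
S037	0	65	82	94	49	200	873	32	212	132	328	489	96	113	112	537	184	7	5	1755	30	90	77	4019	837	0	116	114	31	0
S038	49	6	22	712	0	48	110	36	253	254	289	105	4	84	0	114	21	5	9	499	39	9	117	198	342	28	32	50	36	19
S039	196	77	0	334	3192	144	186	244	1468	219	474	1442	33	150	84	1640	98	81	6	2511	120	55	512	374	2493	192	74	89	44	677
S040	3067	51	298	144	270	44	2591	475	343	180	862	1190	51	128	210	140	114	5	15	406	215	10	249	1228	273	570	425	152	398	1060
S041	119	107	19	632	166	25	20	25	227	184	245	0	23	10	9	203	67	0	13	117	4	11	24	175	123	6	57	3	0	45
S042	2498	0	66	0	47	0	0	163	4924	227	110	588	50	92	425	396	54	3	52	253	31	0	196	246	1163	139	76	0	122	71
S043	218	129	46	515	14	44	0	153	80	20	34	369	8	97	55	59	144	3	13	371	72	31	16	35	735	0	17	6	126	36
S044	497	93	283	355	122	84	0	0	2539	11	974	429	8	112	0	269	52	5	3	464	110	6	38	489	850	6	50	3	206	34
S045	71	6	33	943	67	48	254	59	647	163	485	7325	0	159	7	639	0	4	4	484	291	12	37	424	692	52	5	20	96	52
S046	147	179	655	2559	190	287	1168	1721	629	1139	4803	3525	264	531	185	368	47	124	129	5538	286	31	67	741	1099	57	396	51	994	110
S047	0	216	4326	527	92	0	1943	201	705	718	2146	4101	369	65	342	463	399	25	27	253	256	221	37	565	3405	66	106	22	215	0
S048	2956	44	1951	637	276	0	287	1011	1059	96	505	2580	0	9	0	1115	186	23	52	312	1026	24	217	5134	2080	160	67	12	227	79
S049	116	23	87	55	0	102	412	64	0	15	268	2319	12	20	39	33	11	2	25	863	0	1	10	25	50	0	16	0	121	41
S050	1971	264	14	1568	448	115	466	310	11225	569	0	1056	24	384	105	614	219	3	27	455	104	87	0	4702	818	130	181	41	135	213
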