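unitag	annotation	SD24T	SDTC	SD24S	SDSC
SD173282	So aquaporin TIP2-2	1096	3784	1643	1816
SD231437	So aquaporin PIP1-3/PIP1-4	819	1551	1140	990
SD87583	So aquaporin PIP1-3/PIP1-4	964	956	1186	520
SD119746	So aquaporin TIP2-3	1162	1041	771	530
SD173276	So aquaporin TIP2-2	564	1879	496	0
SD182865	So aquaporin TIP2-2	535	876	501	674
SD87593	So aquaporin PIP1-3/PIP1-4	579	601	750	377
SD80613	So aquaporin TIP1-1	318	234	775	571
SD80612	So aquaporin TIP1-1	437	393	423	453
SD250744	So aquaporin PIP2-1	321	577	265	508
SD19004	Hv aquaporin TIP1-1	422	395	411	210
SD176669	So aquaporin PIP2-6	275	591	310	183
SD243880	So aquaporin PIP2-1	176	326	334	496
SD28080	So aquaporin PIP2-4	406	329	224	312
SD176663	So aquaporin PIP2-6	135	340	227	136
SD241279	So aquaporin PIP1-5	151	184	257	107
SD84960	Ss aquaporin TIP1-1	202	216	29	136
SD243849	So aquaporin PIP2-1	108	123	113	40
SD54852	So aquaporin PIP2-1	107	143	22	52
SD96918	So aquaporin SIP1-2	106	66	96	49
SD96922	So aquaporin SIP1-2	89	43	114	49
SD202395	Pv aquaporin NIP1-1	39	53	40	98
SD243867	So aquaporin PIP2-1	37	42	79	43
SD87586	So aquaporin PIP1-3/PIP1-4	31	54	28	55
SD250859	So aquaporin PIP2-1	39	96	0	32
SD198883	So aquaporin PIP2-5	39	27	30	37
SD21811	So aquaporin SIP1-1	26	16	26	26
SD84958	Ss aquaporin TIP1-1	29	15	9	17
SD217703	So aquaporin NIP3-1	29	15	13	13
SD36243	Hv aquaporin TIP2-2	31	9	12	9
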