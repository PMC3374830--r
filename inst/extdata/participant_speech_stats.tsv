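# Per-participant speech statistics from the published experiments: total
# words and different words spoken by the participant, syllables perceived by
# the robot (all four types, and CVC only), salient items among the top-10
# most frequent CVC words spoken / CVC syllables perceived, and salient words
# uttered by the robot.  NA = not recorded.  Set 2 used a filtered (reduced)
# syllable store, so perception-derived columns are not comparable across
# sets and are conventionally excluded from summaries.
# participant	set	total_words	different_words	syllables_perceived	cvc_perceived	salient_top10_spoken	salient_top10_perceived	salient_uttered
1A	1	282	38	267	96	6	5	5
1B	1	387	76	358	126	4	0	2
1C	1	447	53	284	99	5	3	6
1D	1	481	78	317	116	7	5	4
1E	1	825	84	458	199	5	4	4
1F	1	559	121	453	189	5	3	1
1G	1	398	79	306	117	4	0	0
2A	2	627	53	149	38	5	2	1
2B	2	475	61	98	21	5	2	2
2C	2	876	113	170	45	3	1	1
2D	2	832	113	176	44	4	2	0
2E	2	229	20	86	21	8	2	1
2F	2	729	109	151	28	1	0	1
2G	2	NA	NA	139	35	NA	1	2
3A	3	454	57	316	114	4	3	4
3B	3	165	20	181	61	7	3	2
3C	3	330	56	297	112	8	4	2
3D	3	110	27	171	57	2	2	2
3E	3	297	48	304	118	7	3	3
3F	3	656	135	549	240	3	2	1
4A	4	611	92	426	180	4	4	3
4B	4	368	44	359	154	4	2	1
4C	4	654	84	515	225	6	1	2
4D	4	692	128	488	212	3	2	3
4E	4	704	100	476	203	4	2	2
4F	4	234	65	298	110	8	4	4
4G	4	180	24	227	80	5	3	3
5A	5	558	118	492	213	2	3	2
5B	5	681	145	539	235	5	3	1
5C	5	491	46	301	117	6	3	3
5D	5	221	53	243	85	4	3	2
5E	5	715	120	474	211	4	2	2
5F	5	189	20	139	46	6	5	5
5G	5	83	7	52	13	2	2	2
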