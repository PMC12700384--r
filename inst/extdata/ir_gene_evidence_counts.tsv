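gene	TargetScan	miRDB	miRmap	microT	miRTar2GO	predicted_total	TarBase	miRTarBase	experimental_total	overall_total
INSR	39	55	325	124	147	528	187	4	188	628
IRS1	50	76	100	210	4	315	247	42	276	524
IRS2	39	49	213	107	10	316	227	28	244	492
PIK3R1	53	124	277	199	10	436	230	55	266	609
PIK3R2	8	15	102	27	8	136	99	8	102	229
AKT2	22	8	224	33	33	287	104	31	123	369
AKT3	74	89	291	246	7	529	154	53	190	651
GSK3B	56	100	11	332	6	394	275	64	309	620
PDK1	9	27	28	375	1	405	85	19	97	482
FOXO1	38	94	298	165	9	413	138	69	183	540
MTOR	11	34	83	52	4	128	208	23	215	324
TSC1	65	79	342	140	152	554	180	20	191	632
TSC2	0	0	9	13	9	31	160	3	161	187
AKT1S1	0	0	65	19	0	79	96	4	96	170
SREBF1	7	6	40	19	24	91	173	42	202	276
PDE3B	81	73	132	107	132	373	109	6	110	414
ACACA	0	13	191	63	0	232	267	40	295	498
ACACB	0	24	151	55	19	209	59	15	73	270
ABHD15	16	9	194	33	0	224	33	106	137	328
SLC2A4	22	24	134	37	18	193	33	31	60	227
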