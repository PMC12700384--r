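mirna	TarBase	miRTarBase	TargetScan	total_hits
hsa-miR-16-5p	122	65	45	146
hsa-let-7b-5p	90	46	28	120
hsa-let-7a-5p	83	27	28	113
hsa-miR-27a-3p	80	11	41	106
hsa-miR-17-5p	66	38	27	95
hsa-miR-424-5p	64	16	45	93
hsa-miR-15a-5p	63	31	45	92
hsa-miR-7-5p	77	27	27	91
hsa-let-7c-5p	58	24	28	88
hsa-let-7e-5p	56	34	28	88
hsa-miR-15b-5p	56	33	45	87
hsa-miR-93-5p	53	22	27	78
hsa-let-7d-5p	56	6	28	75
hsa-let-7i-5p	55	6	28	74
hsa-miR-106b-5p	46	25	27	72
hsa-miR-20b-5p	23	17	27	43
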