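mirna	INSR	IRS1	IRS2	PIK3R1	PIK3R2	AKT2	AKT3	GSK3B	PDK1	FOXO1	MTOR	TSC1	TSC2	AKT1S1	SREBF1	PDE3B	ACACA	ACACB	ABHD15	SLC2A4	total	t_score
miR-15a-5p	2	1.4	1.2	1.8	1	1.2	1.8	1.2	1	1.4	1	1.6	1	1	1	1.6	1	1.4	0	1	24.6	1.23
miR-424-5p	2	1.6	1.4	1.8	1	1.2	1.8	1.4	1	1.4	1	1.6	1	1	1	1.6	1	1.4	0	0	24.2	1.21
miR-15b-5p	2	1.4	1.2	1.8	1	1.2	1.8	1.2	0	1.4	1	1.6	1	1	1	1.6	1	1.4	1	0	23.6	1.18
miR-16-5p	2	1.4	1.2	1.8	1	0.2	1.8	1.2	0	1.4	1	1.6	1	1	1	1.6	1	1.4	1	0	22.6	1.13
let-7d-5p	1.6	1	1.6	1	1	1.2	1	1	1	1	1	1.6	1	1	1	1.2	1	1	1	1	22.2	1.11
miR-17-5p	1.6	1	1	1.4	1	1	1.4	1	1	1	1	1.2	1	1	1	2	1	0	1.2	1.4	22.2	1.11
let-7i-5p	1.8	1	1.6	1	1	1.4	1	1	1	1	1	1.6	1	1	1	1.2	1	1	1	0	21.6	1.08
miR-7-5p	1.4	1.8	1.8	1	1	1	1.2	1.2	0.2	1	1.4	1.2	1	1	1	0.2	1	1	1	1.2	21.6	1.08
miR-27a-3p	1.8	1.4	1	1	0	1	1	1.4	1.4	1.6	1	2	1	1	1	1.6	1.2	0	1	0	21.4	1.07
let-7a-5p	1.8	1	1.6	1	1	1.2	1	1	1	1	1	1.6	1	1	1	1.2	1	1	1	0	21.4	1.07
let-7e-5p	1.8	1	1.6	1	1	1.2	1	1	1	1	1	1.6	1	1	1	1.2	1	1	1	0	21.4	1.07
let-7b-5p	1.8	1	1.6	1	1	1.2	1	1	1	1	1	1.4	1	1	1	1.2	1	1	1	0	21.2	1.06
miR-106b-5p	1.4	1	1	1.4	1	1	1.4	1	1	1	1	1	1	0	1	1.8	1	0	1.2	1.4	20.6	1.03
let-7c-5p	1.8	1	1.6	1	1	1.2	1	1	1	1	1	1.6	1	1	1	0.2	1	1	1	0	20.4	1.02
miR-20b-5p	1.6	1	1	1.4	1	0	1.4	1	1	1	1	1.2	1	1	1	2	0	0	1.2	1.4	20.2	1.01
miR-93-5p	1.6	1	1	1.4	1	0	1.4	1	1.2	1	1	1.2	1	0	1	1.6	1	0	1.4	1.4	20.2	1.01
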