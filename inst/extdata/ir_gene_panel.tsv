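gene	entrez	regulator_class
INSR	3643	upstream
IRS1	3667	upstream
IRS2	8660	upstream
PIK3R1	5295	upstream
PIK3R2	5296	upstream
AKT2	208	upstream
AKT3	10000	upstream
GSK3B	2932	downstream
PDK1	5163	downstream
FOXO1	2308	downstream
MTOR	2475	downstream
TSC1	7248	downstream
TSC2	7249	downstream
AKT1S1	84335	downstream
SREBF1	6720	downstream
PDE3B	5140	downstream
ACACA	31	downstream
ACACB	32	downstream
ABHD15	116236	downstream
SLC2A4	6517	downstream
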