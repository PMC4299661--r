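mutation	gene	sift	polyphen	prediction	polarity	charge
T503A	SPG7	0.37	0.001	ND	1/1	0/0
R171Q	NFRKB	0.36	0.2249	ND	2/2	+/0
K267R	CA4	NA	0.314	ND	2/2	+/+
A7S	PDIA3	0.1	0	ND	1/1	0/0
K215R	RBBP4	0.28	0	ND	2/2	+/+
L56M	RET	0.46	0.003	ND	0/0	0/0
R48K	LXN	0.95	0	ND	2/2	+/+
P459L	BACE2	0.62	0.397	ND	1/0	0/0
Y623C	SF3B1	0	0.999	D	0/0	0/0
T663I	SF3B1	0	0.998	D	1/0	0/0
K700E	SF3B1	0	0.999	D	2/2	+/-
E372G	PABPC1	0	0.86	D	2/1	-/0
R374C	PABPC1	0	0.998	D	2/0	+/0
E114G	SDCBP	0	0.234	D	2/1	-/0
R251G	RP2	0.05	0.998	D	2/1	+/0
T207M	AGT	NA	0.991	D	1/0	0/0
E322D	ATF4	0.01	0.998	D	2/2	-/-
T287M	GRB7	0.03	0.895	D	1/0	0/0
C79F	MAVS	0	0.999	D	0/0	0/0
T124I	BAIAP2L1	0.05	0.042	D	1/0	0/0
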