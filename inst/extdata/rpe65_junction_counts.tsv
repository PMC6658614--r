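upstream_exon	library	n_correct	n_skip
1	Human RPE	15898	137
1	ARPE-19 (4 months)	198	8
2	Human RPE	23407	233
2	ARPE-19 (4 months)	189	11
3	Human RPE	27555	112
3	ARPE-19 (4 months)	406	2
4	Human RPE	19375	0
4	ARPE-19 (4 months)	227	0
5	Human RPE	26418	0
5	ARPE-19 (4 months)	169	0
6	Human RPE	31017	937
6	ARPE-19 (4 months)	178	13
7	Human RPE	25913	0
7	ARPE-19 (4 months)	122	0
8	Human RPE	23428	0
8	ARPE-19 (4 months)	199	0
9	Human RPE	20947	0
9	ARPE-19 (4 months)	201	0
10	Human RPE	21608	0
10	ARPE-19 (4 months)	191	0
11	Human RPE	24773	8
11	ARPE-19 (4 months)	208	0
12	Human RPE	27011	0
12	ARPE-19 (4 months)	197	0
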