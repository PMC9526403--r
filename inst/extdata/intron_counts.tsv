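strain	rnl	cox2	nad5	cob	cox1	nad1	Total
B. amorpha GYU-BMZ01	1	1	0	1	1	1	5
B. amorpha GYU-BMZ02	1	1	0	1	1	1	5
B. bassiana YMM	1	0	0	1	0	0	2
B. bassiana GYU-BMZ04	1	1	0	1	0	0	3
B. bassiana ARSEF 8028	1	1	0	1	1	0	4
B. brongniartii GYU-BMZ03	2	1	1	1	2	1	8
B. caledonica ATCC 64970	1	0	0	2	1	0	4
B. pseudobassiana ATCC 90518	1	0	0	0	0	0	1
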