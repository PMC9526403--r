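contig_id	position	strain	gene_content
A	1–5,664	ARSEF_8028	rnl(rps3)-trnT-trnE-trnM3
B1	6,198–6,433	ATCC_90518	trnL1-trnA-trnF-trnK-trnL2
B2	6,414–10,490	ATCC_90518	trnL2-trnQ-trnH-trnM2-nad2-nad3-atp9-cox2-trnR1
B3	10,540–12,490	ATCC_90518	nad4L-nad5
B4	12,470–12,830	ATCC_90518	nad5-cob
B5	12,729–14,308	ATCC_90518	cob-trnC
B6	14,313–17,358	ATCC_90518	cox1
B7	17,429–17,866	ATCC_90518	nad1
B8	17,862–18,968	ATCC_90518	nad1
B9	19,715–20,804	ATCC_90518	nad1-nad4-atp8
B10	20,795–22,128	ATCC_90518	atp8-atp6
B11	22,273–23,966	ATCC_90518	rns-trnY
B12	24,047–25,172	ATCC_90518	trnS-trnN-cox3
B13	25,704–26,318	ATCC_90518	nad6-trnV
C1	6,367–6,996	GYU_BMZ01	trnA-trnF-trnK-trnL2-trnQ-trnH-trnM3
C2	7,011–16,819	GYU_BMZ01	nad2-nad3-atp9-cox2-trnR1-nad4L-nad5-cob
C3	16,818–21,192	GYU_BMZ01	cob-trnC-cox1
C4	21,302–24,514	GYU_BMZ01	nad1-nad4
C5	25,713–28,925	GYU_BMZ01	nad4-atp8-atp6-rns
C6	29,091–29,353	GYU_BMZ01	trnD-trnS-trnN
C7	29,342–30,157	GYU_BMZ01	trnN-cox3
C8	30,529–31,900	GYU_BMZ01	nad6-trnV
C9	31,954–32,191	GYU_BMZ01	trnI-trnS-trnW
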