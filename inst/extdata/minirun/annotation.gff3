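##gff-version 3
##sequence-region contig1 1 42000
##source-version rtracklayer 1.62.0
contig1	rtracklayer	operon	371	2014	.	-	.	ID=OP001;
contig1	rtracklayer	operon	2340	3093	.	+	.	ID=OP002;
contig1	rtracklayer	operon	3616	5744	.	-	.	ID=OP003;
contig1	rtracklayer	operon	6060	6548	.	+	.	ID=OP004;
contig1	rtracklayer	operon	6865	8957	.	-	.	ID=OP005;
contig1	rtracklayer	operon	9450	11624	.	+	.	ID=OP006;
contig1	rtracklayer	operon	11843	13539	.	-	.	ID=OP007;
contig1	rtracklayer	operon	13812	15352	.	-	.	ID=OP008;
contig1	rtracklayer	operon	15843	16832	.	-	.	ID=OP009;
contig1	rtracklayer	operon	17316	19120	.	+	.	ID=OP010;
contig1	rtracklayer	operon	19421	20420	.	-	.	ID=OP011;
contig1	rtracklayer	operon	20721	23204	.	-	.	ID=OP012;
contig1	rtracklayer	operon	24905	27246	.	+	.	ID=OP013;
contig1	rtracklayer	operon	27547	29803	.	+	.	ID=OP014;
contig1	rtracklayer	gene	371	595	.	-	.	ID=CAC0001;Parent=OP001;
contig1	rtracklayer	gene	629	1346	.	-	.	ID=CAC0002;Parent=OP001;
contig1	rtracklayer	gene	1390	2014	.	-	.	ID=CAC0003;Parent=OP001;
contig1	rtracklayer	gene	2340	3093	.	+	.	ID=CAC0004;Parent=OP002;
contig1	rtracklayer	gene	3616	3957	.	-	.	ID=CAC0005;Parent=OP003;
contig1	rtracklayer	gene	4009	4751	.	-	.	ID=CAC0006;Parent=OP003;
contig1	rtracklayer	gene	4783	5471	.	-	.	ID=CAC0007;Parent=OP003;
contig1	rtracklayer	gene	5523	5744	.	-	.	ID=CAC0008;Parent=OP003;
contig1	rtracklayer	gene	6060	6548	.	+	.	ID=CAC0009;Parent=OP004;
contig1	rtracklayer	gene	6865	7638	.	-	.	ID=CAC0010;Parent=OP005;
contig1	rtracklayer	gene	7684	8023	.	-	.	ID=CAC0011;Parent=OP005;
contig1	rtracklayer	gene	8063	8414	.	-	.	ID=CAC0012;Parent=OP005;
contig1	rtracklayer	gene	8465	8957	.	-	.	ID=CAC0013;Parent=OP005;
contig1	rtracklayer	gene	9450	10104	.	+	.	ID=CAC0014;Parent=OP006;
contig1	rtracklayer	gene	10146	10942	.	+	.	ID=CAC0015;Parent=OP006;
contig1	rtracklayer	gene	11001	11238	.	+	.	ID=CAC0016;Parent=OP006;
contig1	rtracklayer	gene	11267	11624	.	+	.	ID=CAC0017;Parent=OP006;
contig1	rtracklayer	gene	11843	12450	.	-	.	ID=CAC0018;Parent=OP007;
contig1	rtracklayer	gene	12500	13006	.	-	.	ID=CAC0019;Parent=OP007;
contig1	rtracklayer	gene	13063	13539	.	-	.	ID=CAC0020;Parent=OP007;
contig1	rtracklayer	gene	13812	14434	.	-	.	ID=CAC0021;Parent=OP008;
contig1	rtracklayer	gene	14489	14973	.	-	.	ID=CAC0022;Parent=OP008;
contig1	rtracklayer	gene	15033	15352	.	-	.	ID=CAC0023;Parent=OP008;
contig1	rtracklayer	gene	15843	16126	.	-	.	ID=CAC0024;Parent=OP009;
contig1	rtracklayer	gene	16161	16524	.	-	.	ID=CAC0025;Parent=OP009;
contig1	rtracklayer	gene	16583	16832	.	-	.	ID=CAC0026;Parent=OP009;
contig1	rtracklayer	gene	17316	17726	.	+	.	ID=CAC0027;Parent=OP010;
contig1	rtracklayer	gene	17774	18282	.	+	.	ID=CAC0028;Parent=OP010;
contig1	rtracklayer	gene	18314	18755	.	+	.	ID=CAC0029;Parent=OP010;
contig1	rtracklayer	gene	18809	19120	.	+	.	ID=CAC0030;Parent=OP010;
contig1	rtracklayer	gene	19421	19779	.	-	.	ID=CAC0031;Parent=OP011;
contig1	rtracklayer	gene	19831	20420	.	-	.	ID=CAC0032;Parent=OP011;
contig1	rtracklayer	gene	20721	21486	.	-	.	ID=CAC0033;Parent=OP012;
contig1	rtracklayer	gene	21518	21954	.	-	.	ID=CAC0034;Parent=OP012;
contig1	rtracklayer	gene	22013	22550	.	-	.	ID=CAC0035;Parent=OP012;
contig1	rtracklayer	gene	22588	22825	.	-	.	ID=CAC0036;Parent=OP012;
contig1	rtracklayer	gene	22869	23204	.	-	.	ID=CAC0037;Parent=OP012;
contig1	rtracklayer	gene	24905	25389	.	+	.	ID=CAC0038;Parent=OP013;
contig1	rtracklayer	gene	25425	26123	.	+	.	ID=CAC0039;Parent=OP013;
contig1	rtracklayer	gene	26168	26710	.	+	.	ID=CAC0040;Parent=OP013;
contig1	rtracklayer	gene	26738	27246	.	+	.	ID=CAC0041;Parent=OP013;
contig1	rtracklayer	gene	27547	28279	.	+	.	ID=CAC0042;Parent=OP014;
contig1	rtracklayer	gene	28315	28690	.	+	.	ID=CAC0043;Parent=OP014;
contig1	rtracklayer	gene	28723	29475	.	+	.	ID=CAC0044;Parent=OP014;
contig1	rtracklayer	gene	29521	29803	.	+	.	ID=CAC0045;Parent=OP014;
contig1	rtracklayer	ncRNA	9058	9349	.	+	.	ID=ksrna01;ncrna_class=known_srna
contig1	rtracklayer	ncRNA	13640	13711	.	+	.	ID=ksrna02;ncrna_class=known_srna
contig1	rtracklayer	ncRNA	2115	2239	.	.	.	ID=PRED0001;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	6649	6764	.	.	.	ID=PRED0002;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	9058	9349	.	.	.	ID=PRED0003;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	13640	13711	.	.	.	ID=PRED0004;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	15453	15742	.	.	.	ID=PRED0005;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	16933	17215	.	.	.	ID=PRED0006;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	20421	20470	.	.	.	ID=PRED0007;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	27497	27546	.	.	.	ID=PRED0008;ncrna_class=predicted_srna
contig1	rtracklayer	ncRNA	23305	24804	.	+	.	ID=struct01;ncrna_class=structural_rna
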