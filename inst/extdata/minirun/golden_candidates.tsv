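id	start	end	left_neighbor	left_strand	right_neighbor	right_strand	qualifying_count	passed_threshold	predictions_in_ior	utr_left_fraction	utr_right_fraction	flank_share	manual_review	neighbor_left_count	neighbor_right_count	status	assigned_name
INTEROP0001	0	370	NA	NA	CAC0001	-	2	FALSE		NA	NA	NA	FALSE	NA	9	not_expressed	NA
INTEROP0002	2014	2339	CAC0003	-	CAC0004	+	9	TRUE	PRED0001	0	0.0438095238095238	0.0438095238095238	FALSE	24	9	novel_srna	sCAC4
INTEROP0003	3093	3615	CAC0004	+	CAC0005	-	0	FALSE		NA	NA	NA	FALSE	9	13	not_expressed	NA
INTEROP0004	5744	6059	CAC0008	-	CAC0009	+	1	FALSE		NA	NA	NA	FALSE	9	13	not_expressed	NA
INTEROP0005	6548	6864	CAC0009	+	CAC0010	-	29	TRUE	PRED0002	0	0	0	FALSE	13	7	novel_srna	sCAC10
INTEROP0006	8957	9449	CAC0013	-	CAC0014	+	10	TRUE		NA	NA	NA	FALSE	6	18	expressed_no_prediction	NA
INTEROP0007	11624	11842	CAC0017	+	CAC0018	-	0	FALSE		NA	NA	NA	FALSE	12	13	not_expressed	NA
INTEROP0008	13539	13811	CAC0020	-	CAC0021	-	17	TRUE		NA	NA	NA	FALSE	5	5	expressed_no_prediction	NA
INTEROP0009	15352	15842	CAC0023	-	CAC0024	-	34	TRUE	PRED0005	0	0.00844036697247706	0.00844036697247706	FALSE	8	10	novel_srna	sCAC24
INTEROP0010	16832	17315	CAC0026	-	CAC0027	+	33	TRUE	PRED0006	0	0	0	FALSE	10	9	novel_srna	sCAC27
INTEROP0011	19120	19420	CAC0030	+	CAC0031	-	0	FALSE		NA	NA	NA	FALSE	18	8	not_expressed	NA
INTEROP0012	20420	20720	CAC0032	-	CAC0033	-	22	TRUE	PRED0007	0.870700170773359	0	0.870700170773359	FALSE	8	11	fp_utr	NA
INTEROP0013	23204	24904	CAC0037	-	CAC0038	+	467	TRUE		NA	NA	NA	FALSE	18	27	expressed_no_prediction	NA
INTEROP0014	27246	27546	CAC0041	+	CAC0042	+	5	TRUE	PRED0008	0	0.885390428211587	0.885390428211587	FALSE	9	17	fp_utr	NA
INTEROP0015	29803	42000	CAC0045	+	NA	NA	2	FALSE		NA	NA	NA	FALSE	16	NA	not_expressed	NA
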