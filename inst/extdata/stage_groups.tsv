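cohort	class	early	late
BRCA	T	T1	T3,T4
BRCA	N	N0	N2,N3
BRCA	M	M0	M1
BRCA	S	S1	S4
COAD	T	T1,T2	T4
COAD	N	N0	N2
COAD	M	M0	M1
COAD	S	S1	S4
HNSC	T	T1	T4
HNSC	N	N0	N2,N3
HNSC	S	S1,S2	S4
KICH	T	T1	T3,T4
KICH	S	S1	S3,S4
KIRC	T	T1	T3,T4
KIRC	N	N0	N1
KIRC	M	M0	M1
KIRC	S	S1	S4
KIRP	T	T1	T3,T4
KIRP	N	N0	N1,N2
KIRP	S	S1	S3,S4
LUSC	T	T1	T3,T4
LUSC	N	N0	N2,N3
LUSC	S	S1	S3,S4
LUAD	T	T1	T3,T4
LUAD	N	N0	N2,N3
LUAD	M	M0	M1
LUAD	S	S1	S3,S4
OV	S	S2	S4
PRAD	T	T2	T3,T4
PRAD	N	N0	N1
SKCM	M	M0	M1
THCA	T	T1	T3,T4
THCA	N	N0	N1
THCA	S	S1	S4
BRCA_ERneg	T	T1	T3,T4
BRCA_ERneg	N	N0	N2,N3
BRCA_ERneg	S	S1	S3,S4
BRCA_ERpos	T	T1	T3,T4
BRCA_ERpos	N	N0	N2,N3
BRCA_ERpos	S	S1	S3,S4
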