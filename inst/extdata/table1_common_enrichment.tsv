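gene_id	lfc_LNv_vs_TH	lfc_LNd_vs_TH	lfc_DN1_vs_TH
cry	4.04	2.78	4.11
vri	3.75	2.68	2.93
tim	2.98	2.43	2.83
npf	4.54	4.46	6.51
CG17777	6.48	6.46	5.81
CG13054	6.35	6.36	6.80
Tdc2	4.10	3.23	3.56
vib	3.91	2.76	4.37
Tbh	4.94	2.33	2.09
Hr51	3.90	3.37	1.00
CG11221	2.40	2.54	1.02
per	2.34	NA	3.01
Clk	3.33	NA	3.80
Pdfr	3.32	NA	4.79
Dh31	4.08	0.28	4.04
MCPH1	2.84	0.78	2.43
CG31714	2.81	0.77	2.78
CG6912	NA	8.54	8.31
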