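marker_id	chromosome	gene	risk_allele	nonrisk_allele	p_value	or	ci_low	ci_high	gwas_selected
rs7903146	10	TCF7L2	T	C	0.00012	2.28	1.50	3.47	TRUE
rs6718526	2	RBMS1	C	T	0.0019	1.76	1.23	2.51	TRUE
rs9465871	6	CDKAL1	C	T	0.016	1.42	1.07	1.90	TRUE
rs9326506	10	ZNF239	A	C	0.021	1.32	1.04	1.67	TRUE
rs2237892	11	KCNQ1	C	T	0.022	1.42	1.05	1.91	TRUE
rs1169288	12	TCF1	G	T	0.042	1.34	1.01	1.79	TRUE
rs9939609	16	FTO	A	T	0.062	1.30	0.99	1.71	TRUE
rs564398	9	CDKN2B	A	G	0.085	1.32	0.96	1.81	TRUE
rs9300039	11	Intergenic	C	A	0.15	1.60	0.84	3.03	TRUE
rs4402960	3	IGF2BP2	T	G	0.16	1.18	0.94	1.50	TRUE
rs2903265	15	ZFAND6	G	A	0.22	0.83	0.62	1.12	TRUE
rs17044137	4	FLJ39370	A	T	0.23	1.21	0.89	1.64	TRUE
rs5015480	10	HHEX	C	T	0.23	1.17	0.90	1.53	TRUE
rs13266634	8	SLC30A8	C	T	0.43	0.89	0.66	1.19	TRUE
rs9282541	9	ABCA1	A	G	0.45	0.80	0.45	1.42	FALSE
rs1801282	3	PPARG	G	C	0.48	0.76	0.36	1.62	TRUE
rs3740878	11	EXT2	A	G	0.51	1.09	0.85	1.39	TRUE
rs10509645	10	IDE	C	A	0.86	0.98	0.75	1.27	TRUE
rs7480010	11	LOC3777761	G	A	0.94	0.99	0.77	1.28	TRUE
rs5215	11	KCNJ11	C	T	0.96	0.99	0.76	1.31	TRUE
rs10506625	12	TSPAN8	C	G	1	1.01	0.71	1.41	TRUE
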