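chrom	start_mb	end_mb	direction	genes
1	16.71	17.14	loss	CROCC MSTP9 ESPNP
1	150.82	150.84	loss	NLCE3C
1	159.75	159.90	loss	FCGR2A FCGR2B FCGR3A HSPA6
1	246.79	246.86	loss	OR2T34 OR2T10 OR2T11
3	196.90	196.96	both	MUC20
4	69.05	69.16	both	UGT2B17
5	0.76	0.87	gain	ZDHHC11
6	0.20	0.32	loss	DUSP22
6	32.56	32.72	both	HLA-DQA1 HLA-DRB1 HLA-DRB5 HLA-DRB6
8	39.35	39.50	both	ADAM3A
10	46.37	47.73	loss	ANXA8 PPYR1 GPRIN2 SYT15 ANTXRL
11	55.12	55.20	gain	OR4P4 OR4C11 OR4S2 OR4C6
12	19.36	19.46	gain	PLEKHA5
14	18.62	19.49	both	OR4K5 OR4K1 OR4N2 OR4K2 OR4Q3 OR4M1
15	18.65	20.08	both	BCL8 NF1P1 OR4N4 OR4M2
15	32.51	32.62	both	GOLGABB
16	31.86	33.53	both	TP53TG3 SLC6A10P HERC2P4
17	41.52	41.57	gain	KIAA1267
17	41.55	42.04	loss	NSF LRRC37A ARL17P1 KIAA1267 LRRC37A2
19	48.20	48.43	loss	PSG1 PSG3 PSG6 PSG7 PSG11
22	22.65	22.72	both	GSTT1
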