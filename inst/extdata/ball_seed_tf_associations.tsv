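feature_id	gene	cohort_id	n	p_value	coefficient	se	adjusted_r2
202098_s_at	PRMT2	GSE7440	99	7.49e-10	0.64	0.09	0.32
202449_s_at	RXRA	GSE7440	99	7.1e-13	0.61	0.07	0.41
204529_s_at	TOX	GSE7440	99	8.58e-07	0.33	0.06	0.21
205038_at	IKZF1	GSE7440	99	4.89e-05	0.38	0.09	0.15
209107_x_at	NCOA1	GSE7440	99	1.69e-10	0.84	0.12	0.34
209930_s_at	NFE2	GSE7440	99	2.64e-09	0.38	0.06	0.3
210249_s_at	NCOA1	GSE7440	99	2.93e-13	0.92	0.11	0.42
212330_at	TFDP1	GSE7440	99	2.94e-12	0.51	0.06	0.39
212331_at	RBL2	GSE7440	99	8.99e-10	0.58	0.09	0.32
216241_s_at	TCEA1	GSE7440	99	8.56e-08	0.65	0.11	0.25
43544_at	MED16	GSE7440	99	3.64e-11	0.74	0.1	0.36
202098_s_at	PRMT2	GSE10255	161	0.01	0.4	0.15	0.04
202449_s_at	RXRA	GSE10255	161	0.01	0.2	0.08	0.03
204529_s_at	TOX	GSE10255	161	0.000756	0.16	0.05	0.06
205038_at	IKZF1	GSE10255	161	0.03	0.26	0.12	0.02
209107_x_at	NCOA1	GSE10255	161	0.0041	0.57	0.2	0.04
209930_s_at	NFE2	GSE10255	161	4.8e-15	0.26	0.03	0.32
210249_s_at	NCOA1	GSE10255	161	0.00184	0.51	0.16	0.05
212330_at	TFDP1	GSE10255	161	0.00135	0.15	0.05	0.06
212331_at	RBL2	GSE10255	161	0.0045	0.37	0.13	0.04
216241_s_at	TCEA1	GSE10255	161	0.00365	0.49	0.17	0.05
43544_at	MED16	GSE10255	161	9.86e-09	0.72	0.12	0.18
202098_s_at	PRMT2	GSE10792	160	5.74e-07	0.53	0.1	0.26
202449_s_at	RXRA	GSE10792	160	0.01	0.22	0.08	0.07
204529_s_at	TOX	GSE10792	160	0.02	0.16	0.07	0.05
205038_at	IKZF1	GSE10792	160	0.03	0.33	0.14	0.05
209107_x_at	NCOA1	GSE10792	160	0.02	0.48	0.21	0.05
209930_s_at	NFE2	GSE10792	160	0.00167	0.24	0.07	0.11
210249_s_at	NCOA1	GSE10792	160	0.04	0.44	0.21	0.04
212330_at	TFDP1	GSE10792	160	8.94e-07	0.29	0.06	0.26
212331_at	RBL2	GSE10792	160	0.000612	0.64	0.18	0.13
216241_s_at	TCEA1	GSE10792	160	0.00296	0.84	0.28	0.1
43544_at	MED16	GSE10792	160	0.000579	0.51	0.14	0.13
202098_s_at	PRMT2	GSE11877	207	4.93e-09	0.39	0.06	0.15
202449_s_at	RXRA	GSE11877	207	0.00165	0.17	0.05	0.04
204529_s_at	TOX	GSE11877	207	0.00219	0.17	0.05	0.04
205038_at	IKZF1	GSE11877	207	1.03e-06	0.33	0.07	0.11
209107_x_at	NCOA1	GSE11877	207	0.000102	0.49	0.12	0.07
209930_s_at	NFE2	GSE11877	207	1.6e-05	0.15	0.03	0.08
210249_s_at	NCOA1	GSE11877	207	0.000121	0.46	0.12	0.07
212330_at	TFDP1	GSE11877	207	0.00224	0.2	0.06	0.04
212331_at	RBL2	GSE11877	207	8.65e-13	0.59	0.08	0.22
216241_s_at	TCEA1	GSE11877	207	0.000196	0.43	0.11	0.06
43544_at	MED16	GSE11877	207	2.71e-07	0.34	0.06	0.12
202098_s_at	PRMT2	GSE13351	107	4.53e-09	0.58	0.09	0.31
202449_s_at	RXRA	GSE13351	107	0.000381	0.24	0.07	0.12
204529_s_at	TOX	GSE13351	107	0.00394	0.19	0.07	0.08
205038_at	IKZF1	GSE13351	107	0.00102	0.31	0.09	0.1
209107_x_at	NCOA1	GSE13351	107	1.8e-05	0.91	0.2	0.18
209930_s_at	NFE2	GSE13351	107	1.89e-06	0.28	0.06	0.22
210249_s_at	NCOA1	GSE13351	107	3.54e-05	0.82	0.19	0.16
212330_at	TFDP1	GSE13351	107	0.00172	0.2	0.06	0.09
212331_at	RBL2	GSE13351	107	3.46e-12	0.67	0.08	0.41
216241_s_at	TCEA1	GSE13351	107	4.43e-05	0.58	0.14	0.16
43544_at	MED16	GSE13351	107	9.53e-06	0.45	0.1	0.19
202098_s_at	PRMT2	GSE13425	190	9.14e-05	0.36	0.09	0.09
202449_s_at	RXRA	GSE13425	190	1.01e-06	0.39	0.08	0.14
204529_s_at	TOX	GSE13425	190	0.0053	0.25	0.09	0.04
205038_at	IKZF1	GSE13425	190	0.00118	0.31	0.09	0.06
209107_x_at	NCOA1	GSE13425	190	0.000207	0.66	0.17	0.08
209930_s_at	NFE2	GSE13425	190	0.00299	0.18	0.06	0.05
210249_s_at	NCOA1	GSE13425	190	0.00379	0.52	0.18	0.05
212330_at	TFDP1	GSE13425	190	0.00578	0.2	0.07	0.04
212331_at	RBL2	GSE13425	190	1.32e-06	0.54	0.11	0.14
216241_s_at	TCEA1	GSE13425	190	0.000331	0.54	0.15	0.08
43544_at	MED16	GSE13425	190	0.00147	0.33	0.1	0.06
202098_s_at	PRMT2	GSE33315	575	4.32e-17	0.56	0.06	0.13
202449_s_at	RXRA	GSE33315	575	9.08e-05	0.16	0.04	0.03
204529_s_at	TOX	GSE33315	575	0.00321	0.11	0.04	0.02
205038_at	IKZF1	GSE33315	575	1.88e-09	0.34	0.05	0.07
209107_x_at	NCOA1	GSE33315	575	1.38e-12	0.75	0.1	0.1
209930_s_at	NFE2	GSE33315	575	1.32e-26	0.22	0.02	0.21
210249_s_at	NCOA1	GSE33315	575	8.79e-14	0.67	0.09	0.11
212330_at	TFDP1	GSE33315	575	3.64e-16	0.24	0.03	0.13
212331_at	RBL2	GSE33315	575	1.81e-23	0.68	0.06	0.19
216241_s_at	TCEA1	GSE33315	575	8.81e-11	0.57	0.09	0.08
43544_at	MED16	GSE33315	575	5.83e-21	0.6	0.06	0.17
202098_s_at	PRMT2	GSE635	173	2.01e-06	0.41	0.08	0.12
202449_s_at	RXRA	GSE635	173	0.000138	0.28	0.07	0.08
204529_s_at	TOX	GSE635	173	5.41e-07	0.29	0.05	0.13
205038_at	IKZF1	GSE635	173	0.02	0.2	0.09	0.02
209107_x_at	NCOA1	GSE635	173	0.00365	0.51	0.17	0.04
209930_s_at	NFE2	GSE635	173	0.00123	0.14	0.04	0.05
210249_s_at	NCOA1	GSE635	173	0.00297	0.49	0.16	0.04
212330_at	TFDP1	GSE635	173	0.00286	0.18	0.06	0.05
212331_at	RBL2	GSE635	173	3.44e-05	0.44	0.1	0.09
216241_s_at	TCEA1	GSE635	173	6.07e-05	0.64	0.16	0.08
43544_at	MED16	GSE635	173	0.00101	0.3	0.09	0.06
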