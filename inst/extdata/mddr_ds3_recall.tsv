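class_id	TAN_1	BIN_1	BINRF_1	TAN_5	BIN_5	BINRF_5
09249	25.09	15.33	15.51	40.21	25.72	29.08
12455	7.7	9.37	11.59	19.08	14.65	16.77
12464	9.02	8.45	11.67	14.56	16.55	27.1
31281	27.53	18.29	44.48	44	28.29	59.9
43210	11.1	7.34	9.41	26.37	14.41	21.27
71522	2.35	4.08	11.39	6.28	8.44	23.62
75721	24.02	20.41	28.24	28.97	30.02	56.39
78331	6.27	7.51	10.11	15.79	12.03	18.82
78348	4.69	9.79	8.99	13.16	20.76	24.15
78351	4.31	13.68	16.64	10.55	12.94	20.16
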