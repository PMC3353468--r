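class_id	TAN_1	BIN_1	BINRF_1	TAN_5	BIN_5	BINRF_5
31420	55.84	74.08	81.8	85.49	87.61	84.12
71523	22.26	28.26	43.86	42.7	52.72	68.72
37110	12.54	26.05	41.25	24.11	48.2	71.05
31432	33.36	39.23	46.5	68.2	77.57	91.59
42731	16.24	21.68	28.13	32.81	26.63	42.39
06233	14.23	14.06	16.75	27.01	23.49	32.93
06245	10.06	6.31	10.04	22.9	14.86	28.8
07701	8.91	11.45	19.75	23.1	27.79	41.24
06235	11.87	10.84	12.45	24.54	23.78	31.89
78374	16.75	14.25	25.49	24.26	20.2	39.18
78331	8.05	6.03	8.14	16.83	11.8	11.20
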