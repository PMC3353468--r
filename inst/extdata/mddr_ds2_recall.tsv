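class_id	TAN_1	BIN_1	BINRF_1	TAN_5	BIN_5	BINRF_5
07707	78.3	72.18	72.33	91.08	74.81	74.17
07708	74.01	96	100	88.52	99.61	100
31420	46.44	79.82	82.71	77.6	95.46	97.15
42710	57.22	76.27	95.36	67.59	92.55	99.36
64100	93.22	88.43	87.75	97.89	99.22	98.93
64200	63.39	70.18	71.79	89.82	99.2	99.12
64220	73.56	68.32	82.47	92.05	91.32	98.89
64500	60.75	81.2	96.56	74.98	94.96	99.28
64350	76.69	81.89	93.67	90.34	91.47	98.24
75755	95.99	98.06	98.26	98.78	98.33	98.33
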