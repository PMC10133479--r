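node_a	node_b	combined_score	textmining_score	experimental_score
dde_2265	dde_0526	0.95	0.81	0.90
dde_2265	dde_0527	0.94	0.78	0.88
dde_2265	dde_1110	0.92	0.74	0.85
dde_0526	dde_0527	0.99	0.90	0.97
dde_0526	dde_0762	0.93	0.72	0.86
dde_0527	dde_0762	0.91	0.70	0.84
dde_1109	dde_1110	0.98	0.88	0.95
dde_1110	dde_0526	0.74	0.52	0.60
dde_2066	rpsM	0.88	0.66	0.79
dde_2066	rplF	0.86	0.63	0.75
dde_2066	secY	0.71	0.45	0.58
rpsM	rplF	0.97	0.85	0.93
rplF	secY	0.90	0.69	0.82
upp	pyrB	0.89	0.67	0.80
upp	ndk	0.84	0.61	0.72
pyrB	ndk	0.87	0.64	0.77
dde_0155	dde_3518	0.93	0.73	0.85
dde_0155	dde_3519	0.92	0.71	0.83
dde_3518	dde_3519	0.96	0.83	0.91
dde_1208	dde_1209	0.99	0.91	0.98
dde_1209	dde_0717	0.78	0.55	0.64
dde_0717	dde_0652	0.90	0.68	0.81
dde_1208	dde_0652	0.76	0.53	0.62
dde_2134	dde_2135	0.98	0.87	0.96
dde_2135	dde_2137	0.92	0.72	0.84
dde_2134	dde_2137	0.91	0.70	0.83
dde_2265	dde_2066	0.67	0.49	0.41
dde_2265	upp	0.64	0.47	0.38
dde_2265	dde_0155	0.62	0.45	0.36
dde_2265	dde_1209	0.69	0.51	0.44
dde_2265	dde_2134	0.61	0.44	0.35
dde_0526	dde_2134	0.58	0.41	0.33
dde_0527	dde_2135	0.57	0.40	0.31
dde_1209	dde_1110	0.72	0.54	0.47
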