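Kinase	Observed	SamplingAvg	SD	Z
PKA	42	28.55	2.97	4.52
JNK	10	22.79	2.90	-4.41
ERK	15	28.05	3.00	-4.35
P38	13	24.59	2.89	-4.01
RSK	51	39.43	2.98	3.88
DMPK	59	48.99	2.59	3.86
DYRK	15	25.76	2.86	-3.77
PDK1	19	29.90	2.92	-3.73
PKG	33	22.89	2.84	3.56
AKT	28	18.99	2.74	3.29
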