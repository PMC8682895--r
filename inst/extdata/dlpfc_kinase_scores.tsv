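Kinase	Observed	SamplingAvg	SD	Z
CDK	30	39.76	2.62	-3.72
PDK1	15	24.97	2.86	-3.48
STE7	11	20.26	2.80	-3.30
P38	12	20.69	2.85	-3.05
JNK	11	19.19	2.75	-2.98
PLK	11	18.21	2.76	-2.61
DYRK	14	21.38	2.88	-2.56
ERK	16	23.36	2.91	-2.53
BARK2	3	1.16	0.84	2.19
NMO	1	4.38	1.55	-2.18
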