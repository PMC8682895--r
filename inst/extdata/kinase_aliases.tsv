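alias	canonical
ERK1	ERK
ERK2	ERK
MAPK1	ERK
MAPK3	ERK
P38A	P38
MAPK14	P38
JNK1	JNK
JNK2	JNK
MAPK8	JNK
PKB	AKT
AKT1	AKT
GRK2	BARK2
MAP2K1	STE7
MEK1	STE7
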