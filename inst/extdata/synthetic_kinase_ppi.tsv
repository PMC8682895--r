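from	to
AKT	DYRK
AKT	MARK
AKT	PKC
AKT	RSK
BARK2	CDK
BARK2	JNK
BARK2	NMO
BARK2	PKA
BARK2	PKC
BARK2	RSK
CDK	DYRK
CDK	ERK
CDK	NMO
CDK	PDK1
CDK	PLK
DYRK	PDK1
DYRK	PKA
DYRK	STE7
ERK	PLK
ERK	STE7
JNK	PKC
MARK	PLK
NMO	PDK1
NMO	PKC
P38	PDK1
P38	RSK
P38	STE7
PKC	RSK
PLK	STE7
RSK	STE7
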