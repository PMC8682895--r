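peptideId	kinase
PEP_038	AKT
PEP_045	AKT
PEP_036	AKT
PEP_048	AKT
PEP_005	AKT
PEP_031	AKT
PEP_044	AKT
PEP_058	AKT
PEP_019	AKT
PEP_010	AKT
PEP_054	AKT
PEP_018	AKT
PEP_034	AKT
PEP_012	AKT
PEP_056	AKT
PEP_081	AKT
PEP_035	AKT
PEP_071	AKT
PEP_003	AKT
PEP_042	AKT
PEP_061	AKT
PEP_082	AKT
PEP_008	AKT
PEP_050	AKT
PEP_002	AKT
PEP_045	BARK2
PEP_061	BARK2
PEP_005	BARK2
PEP_073	CDK
PEP_082	CDK
PEP_071	CDK
PEP_027	CDK
PEP_064	CDK
PEP_050	CDK
PEP_069	CDK
PEP_029	CDK
PEP_068	CDK
PEP_080	CDK
PEP_017	CDK
PEP_008	CDK
PEP_009	CDK
PEP_063	CDK
PEP_003	CDK
PEP_061	CDK
PEP_077	CDK
PEP_047	CDK
PEP_052	CDK
PEP_036	CDK
PEP_025	CDK
PEP_031	CDK
PEP_015	CDK
PEP_001	CDK
PEP_024	CDK
PEP_044	CDK
PEP_006	CDK
PEP_045	CDK
PEP_004	CDK
PEP_076	CDK
PEP_084	CDK
PEP_038	CDK
PEP_016	CDK
PEP_058	CDK
PEP_049	CDK
PEP_023	CDK
PEP_078	CDK
PEP_074	CDK
PEP_084	DYRK
PEP_035	DYRK
PEP_020	DYRK
PEP_079	DYRK
PEP_049	DYRK
PEP_021	DYRK
PEP_053	DYRK
PEP_036	DYRK
PEP_045	DYRK
PEP_026	DYRK
PEP_044	DYRK
PEP_003	DYRK
PEP_030	DYRK
PEP_019	DYRK
PEP_076	DYRK
PEP_027	DYRK
PEP_038	DYRK
PEP_052	DYRK
PEP_033	DYRK
PEP_082	DYRK
PEP_028	ERK
PEP_021	ERK
PEP_034	ERK
PEP_068	ERK
PEP_015	ERK
PEP_059	ERK
PEP_057	ERK
PEP_033	ERK
PEP_073	ERK
PEP_013	ERK
PEP_051	ERK
PEP_083	ERK
PEP_018	ERK
PEP_044	ERK
PEP_084	ERK
PEP_041	ERK
PEP_058	ERK
PEP_049	ERK
PEP_079	ERK
PEP_066	ERK
PEP_024	ERK
PEP_014	ERK
PEP_053	JNK
PEP_058	JNK
PEP_038	JNK
PEP_044	JNK
PEP_002	JNK
PEP_084	JNK
PEP_068	JNK
PEP_031	JNK
PEP_079	JNK
PEP_034	JNK
PEP_056	JNK
PEP_070	JNK
PEP_047	JNK
PEP_023	JNK
PEP_074	JNK
PEP_017	JNK
PEP_004	JNK
PEP_073	JNK
PEP_011	MARK
PEP_022	MARK
PEP_006	MARK
PEP_083	MARK
PEP_038	MARK
PEP_033	MARK
PEP_029	MARK
PEP_068	MARK
PEP_019	MARK
PEP_067	NMO
PEP_063	NMO
PEP_005	NMO
PEP_070	NMO
PEP_015	NMO
PEP_074	P38
PEP_070	P38
PEP_043	P38
PEP_055	P38
PEP_036	P38
PEP_018	P38
PEP_032	P38
PEP_079	P38
PEP_080	P38
PEP_030	P38
PEP_019	P38
PEP_083	P38
PEP_044	P38
PEP_065	P38
PEP_073	P38
PEP_068	P38
PEP_045	P38
PEP_075	P38
PEP_002	P38
PEP_048	PDK1
PEP_062	PDK1
PEP_014	PDK1
PEP_047	PDK1
PEP_040	PDK1
PEP_074	PDK1
PEP_007	PDK1
PEP_023	PDK1
PEP_045	PDK1
PEP_076	PDK1
PEP_072	PDK1
PEP_044	PDK1
PEP_026	PDK1
PEP_083	PDK1
PEP_042	PDK1
PEP_070	PDK1
PEP_028	PDK1
PEP_024	PDK1
PEP_008	PDK1
PEP_016	PDK1
PEP_001	PDK1
PEP_052	PDK1
PEP_005	PDK1
PEP_069	PDK1
PEP_001	PKA
PEP_050	PKA
PEP_022	PKA
PEP_064	PKA
PEP_067	PKA
PEP_060	PKA
PEP_053	PKA
PEP_035	PKA
PEP_066	PKA
PEP_013	PKA
PEP_058	PKA
PEP_007	PKA
PEP_075	PKA
PEP_062	PKA
PEP_084	PKA
PEP_025	PKA
PEP_068	PKA
PEP_077	PKA
PEP_016	PKA
PEP_039	PKA
PEP_037	PKA
PEP_055	PKA
PEP_071	PKA
PEP_009	PKA
PEP_021	PKA
PEP_006	PKA
PEP_018	PKA
PEP_019	PKC
PEP_036	PKC
PEP_009	PKC
PEP_045	PKC
PEP_051	PKC
PEP_055	PKC
PEP_062	PKC
PEP_040	PKC
PEP_002	PKC
PEP_076	PKC
PEP_012	PKC
PEP_054	PKC
PEP_003	PKC
PEP_021	PKC
PEP_056	PKC
PEP_028	PKC
PEP_052	PKC
PEP_058	PKC
PEP_084	PKC
PEP_044	PKC
PEP_030	PKC
PEP_068	PKC
PEP_010	PKC
PEP_025	PKC
PEP_001	PKC
PEP_023	PKC
PEP_014	PKC
PEP_053	PKC
PEP_071	PKC
PEP_016	PKC
PEP_064	PLK
PEP_038	PLK
PEP_009	PLK
PEP_082	PLK
PEP_041	PLK
PEP_067	PLK
PEP_043	PLK
PEP_030	PLK
PEP_079	PLK
PEP_037	PLK
PEP_060	PLK
PEP_026	PLK
PEP_033	PLK
PEP_059	PLK
PEP_006	PLK
PEP_065	PLK
PEP_076	PLK
PEP_055	RSK
PEP_063	RSK
PEP_072	RSK
PEP_078	RSK
PEP_027	RSK
PEP_032	RSK
PEP_031	RSK
PEP_053	RSK
PEP_058	RSK
PEP_012	RSK
PEP_042	RSK
PEP_041	RSK
PEP_084	RSK
PEP_048	RSK
PEP_009	RSK
PEP_025	RSK
PEP_018	RSK
PEP_008	RSK
PEP_036	RSK
PEP_034	RSK
PEP_081	RSK
PEP_057	RSK
PEP_068	RSK
PEP_024	RSK
PEP_047	RSK
PEP_067	RSK
PEP_001	RSK
PEP_045	RSK
PEP_026	RSK
PEP_016	RSK
PEP_030	RSK
PEP_020	RSK
PEP_007	RSK
PEP_049	RSK
PEP_051	RSK
PEP_077	STE7
PEP_001	STE7
PEP_010	STE7
PEP_028	STE7
PEP_054	STE7
PEP_039	STE7
PEP_014	STE7
PEP_069	STE7
PEP_031	STE7
PEP_049	STE7
PEP_012	STE7
PEP_057	STE7
PEP_055	STE7
PEP_062	STE7
PEP_076	STE7
PEP_011	STE7
PEP_034	STE7
PEP_013	STE7
PEP_020	STE7
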