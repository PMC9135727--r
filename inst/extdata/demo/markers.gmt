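cell_01	na	MKR0010	G0002	G0077	G0050	G0117	G0019	MKR0020	G0059	MKR0018	G0120	G0044	MKR0009	G0005	G0051	G0045	MKR0029	MKR0024	G0031	G0001	MKR0002
cell_02	na	G0011	G0032	G0025	G0104	G0079	G0107	G0026	G0067	G0096	G0022	MKR0013	G0092	G0057	MKR0003	G0017	G0076	MKR0005	G0093	G0061	MKR0027
cell_03	na	G0075	G0003	G0040	MKR0017	MKR0030	G0035	MKR0004	G0105	G0095	MKR0016	G0053	G0030	MKR0019	G0027	G0063	G0008	G0070	G0042	G0060	G0018
cell_04	na	G0034	G0013	MKR0007	G0088	G0072	G0041	G0103	G0007	MKR0025	MKR0023	G0100	MKR0014	MKR0026	G0038	G0012	G0052	G0064	G0073	G0036	G0043
cell_05	na	G0109	G0114	G0056	G0058	G0091	G0010	G0039	G0037	MKR0022	G0101	G0116	G0119	MKR0021	MKR0008	MKR0001	G0062	G0090	MKR0028	G0078	MKR0015
cell_06	na	G0004	MKR0006	G0071	G0009	G0108	G0055	G0006	G0065	G0047	G0066	G0046	G0068	G0102	G0098	G0049	G0069	G0015	MKR0011	G0014	MKR0012
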