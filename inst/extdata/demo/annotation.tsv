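gene_id	type
LNC0001	lncRNA
LNC0002	lncRNA
LNC0003	lncRNA
LNC0004	lncRNA
LNC0005	lncRNA
LNC0006	lncRNA
LNC0007	lncRNA
LNC0008	lncRNA
LNC0009	lncRNA
LNC0010	lncRNA
LNC0011	lncRNA
LNC0012	lncRNA
LNC0013	lncRNA
LNC0014	lncRNA
LNC0015	lncRNA
LNC0016	lncRNA
LNC0017	lncRNA
LNC0018	lncRNA
LNC0019	lncRNA
LNC0020	lncRNA
LNC0021	lncRNA
LNC0022	lncRNA
LNC0023	lncRNA
LNC0024	lncRNA
LNC0025	lncRNA
LNC0026	lncRNA
LNC0027	lncRNA
LNC0028	lncRNA
LNC0029	lncRNA
LNC0030	lncRNA
LNC0031	lncRNA
LNC0032	lncRNA
LNC0033	lncRNA
LNC0034	lncRNA
LNC0035	lncRNA
LNC0036	lncRNA
LNC0037	lncRNA
LNC0038	lncRNA
LNC0039	lncRNA
LNC0040	lncRNA
G0001	mRNA
G0002	mRNA
G0003	mRNA
G0004	mRNA
G0005	mRNA
G0006	mRNA
G0007	mRNA
G0008	mRNA
G0009	mRNA
G0010	mRNA
G0011	mRNA
G0012	mRNA
G0013	mRNA
G0014	mRNA
G0015	mRNA
G0016	mRNA
G0017	mRNA
G0018	mRNA
G0019	mRNA
G0020	mRNA
G0021	mRNA
G0022	mRNA
G0023	mRNA
G0024	mRNA
G0025	mRNA
G0026	mRNA
G0027	mRNA
G0028	mRNA
G0029	mRNA
G0030	mRNA
G0031	mRNA
G0032	mRNA
G0033	mRNA
G0034	mRNA
G0035	mRNA
G0036	mRNA
G0037	mRNA
G0038	mRNA
G0039	mRNA
G0040	mRNA
G0041	mRNA
G0042	mRNA
G0043	mRNA
G0044	mRNA
G0045	mRNA
G0046	mRNA
G0047	mRNA
G0048	mRNA
G0049	mRNA
G0050	mRNA
G0051	mRNA
G0052	mRNA
G0053	mRNA
G0054	mRNA
G0055	mRNA
G0056	mRNA
G0057	mRNA
G0058	mRNA
G0059	mRNA
G0060	mRNA
G0061	mRNA
G0062	mRNA
G0063	mRNA
G0064	mRNA
G0065	mRNA
G0066	mRNA
G0067	mRNA
G0068	mRNA
G0069	mRNA
G0070	mRNA
G0071	mRNA
G0072	mRNA
G0073	mRNA
G0074	mRNA
G0075	mRNA
G0076	mRNA
G0077	mRNA
G0078	mRNA
G0079	mRNA
G0080	mRNA
G0081	mRNA
G0082	mRNA
G0083	mRNA
G0084	mRNA
G0085	mRNA
G0086	mRNA
G0087	mRNA
G0088	mRNA
G0089	mRNA
G0090	mRNA
G0091	mRNA
G0092	mRNA
G0093	mRNA
G0094	mRNA
G0095	mRNA
G0096	mRNA
G0097	mRNA
G0098	mRNA
G0099	mRNA
G0100	mRNA
G0101	mRNA
G0102	mRNA
G0103	mRNA
G0104	mRNA
G0105	mRNA
G0106	mRNA
G0107	mRNA
G0108	mRNA
G0109	mRNA
G0110	mRNA
G0111	mRNA
G0112	mRNA
G0113	mRNA
G0114	mRNA
G0115	mRNA
G0116	mRNA
G0117	mRNA
G0118	mRNA
G0119	mRNA
G0120	mRNA
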