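pathway_01	na	G0077	G0005	G0031	G0059	G0120	G0044	G0002	G0045	G0019	G0001	G0051	G0050
pathway_02	na	G0032	G0067	G0025	G0011	G0107	G0092	G0061	G0076	G0093	G0057	G0096	G0079
pathway_03	na	G0075	G0042	G0070	G0003	G0035	G0105	G0018	G0063	G0095	G0008	G0040	G0060
pathway_04	na	G0038	G0007	G0013	G0052	G0072	G0088	G0073	G0036	G0041	G0103	G0012	G0034
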