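sample_id	time	event
S001	160.934237838796	1
S002	4008.41138213055	0
S003	2291.11722134885	1
S004	314.10012311312	1
S005	1725.34182084208	1
S006	339.4289746313	1
S007	403.123927299146	1
S008	1005.58735267359	0
S009	194.381584069508	1
S010	55.0926061138767	1
S011	194.200712008661	1
S012	423.786129128446	1
S013	419.89742507174	0
S014	4.21870926715819	0
S015	1496.04955096204	0
S016	3532.9491691899	0
S017	529.681179981983	1
S018	167.715493981601	1
S019	515.71184358778	1
S020	12.2027275659221	1
S021	648.898594962589	1
S022	752.867173619	0
S023	406.099353230187	1
S024	1715.92275569422	1
S025	273.412279759183	1
S026	2717.21241323098	1
S027	475.390420232593	1
S028	1884.01735635278	1
S029	449.215458284434	0
S030	851.810315907093	1
S031	644.558108308569	1
S032	191.343275887953	1
S033	1897.13085537775	1
S034	907.695404153292	1
S035	315.188377091224	1
S036	1673.42890594276	1
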