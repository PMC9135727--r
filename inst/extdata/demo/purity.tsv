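sample_id	purity
S001	0.775654
S002	0.589512
S003	0.831752
S004	0.669009
S005	0.647344
S006	0.572787
S007	0.736513
S008	0.493515
S009	0.757265
S010	0.595974
S011	0.848838
S012	0.924772
S013	0.759716
S014	0.751747
S015	0.856297
S016	0.702331
S017	0.851966
S018	0.74622
S019	0.549607
S020	0.765373
S021	0.924515
S022	0.540159
S023	0.919653
S024	0.610512
S025	0.737778
S026	0.61047
S027	0.602942
S028	0.499591
S029	0.468249
S030	0.966419
S031	0.83893
S032	0.679142
S033	0.492603
S034	0.941504
S035	0.615004
S036	0.606772
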