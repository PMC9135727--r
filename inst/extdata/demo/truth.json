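{"driver_lncs":["LNC0007","LNC0009","LNC0011","LNC0018","LNC0030","LNC0038","LNC0039","LNC0040"],"confounded_lncs":["LNC0004","LNC0005","LNC0006","LNC0010","LNC0012","LNC0024","LNC0025","LNC0029"],"null_lncs":["LNC0001","LNC0002","LNC0003","LNC0008","LNC0013","LNC0014","LNC0015","LNC0016","LNC0017","LNC0019","LNC0020","LNC0021","LNC0022","LNC0023","LNC0026","LNC0027","LNC0028","LNC0031","LNC0032","LNC0033","LNC0034","LNC0035","LNC0036","LNC0037"],"driver_pathway":{"LNC0007":"pathway_01","LNC0009":"pathway_02","LNC0011":"pathway_03","LNC0018":"pathway_04","LNC0030":"pathway_01","LNC0038":"pathway_02","LNC0039":"pathway_03","LNC0040":"pathway_04"},"pathway_cell":{"pathway_01":"cell_01","pathway_02":"cell_02","pathway_03":"cell_03","pathway_04":"cell_04"},"subtype_labels":{"S001":2,"S002":1,"S003":2,"S004":1,"S005":2,"S006":2,"S007":1,"S008":1,"S009":1,"S010":2,"S011":2,"S012":2,"S013":2,"S014":1,"S015":2,"S016":1,"S017":2,"S018":2,"S019":1,"S020":2,"S021":1,"S022":1,"S023":1,"S024":1,"S025":1,"S026":1,"S027":2,"S028":1,"S029":2,"S030":1,"S031":1,"S032":2,"S033":2,"S034":2,"S035":2,"S036":1},"risk_genes":{"G0023":0.47111165355891,"G0106":-0.662124299164861,"G0111":-0.786665503121913,"G0115":0.515857542864978},"responsive_mrnas":["G0021","G0081","G0084","G0054","G0082","G0110","G0097","G0111","G0083","G0085","G0074","G0112","G0020","G0115","G0106","G0094","G0089","G0028","G0024","G0023","G0118","G0080","G0016","G0087","G0029","G0099","G0048","G0033","G0113","G0086"],"gamma":2,"delta":2,"K_true":2,"beta_scale":1,"censor_frac":0.25}
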