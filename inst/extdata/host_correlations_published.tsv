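dataset	total	positive	gt_025	gt_05	fdr
MM	309	199	78	33	34
ALL	147	81	53	20	8
ALZ	148	77	47	21	0
PRO	170	138	56	13	60
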