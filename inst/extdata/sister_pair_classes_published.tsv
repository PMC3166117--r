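dataset	A	AC	C	NOT_EXPRESSED
PRO	19	75	1	0
MM	26	197	13	1
ALZ	10	7	10	10
ALL	9	19	4	0
MCN	65	144	25	3
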