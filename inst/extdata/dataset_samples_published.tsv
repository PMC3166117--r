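dataset	geo_accession	n_samples	in_combined_heatmap
MM	GSE17498	39	TRUE
ALL	GSE14834	19	FALSE
ALZ	GSE16759	16	FALSE
PRO	GSE21032	140	TRUE
MCN	GSE14985	32	TRUE
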