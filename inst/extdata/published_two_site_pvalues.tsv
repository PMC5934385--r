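variant_id	gene	outcome	p_site1	p_site2	combined_p_published
rs2564	VEGFA	response_binary	2.7e-2	1.9e-2	4.4e-3
rs7044702	NTRK2	response_binary	4.5e-2	8.2e-3	3.3e-3
rs2148252	VEGFA	response_pct	9.1e-2	3.8e-3	3.1e-3
chr11:27682769:D	BDNF	remitted	4.9e-3	8.5e-3	4.7e-4
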