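subunit	position	ecoli_position	ecoli_mod_type
SSU	1664	1402	m4Cm
SSU	1807	1498	m3U
SSU	1827	1518	m62A
SSU	1828	1519	m62A
LSU	2030	1835	Gm
LSU	2257	1939	m5U
LSU	2560	2251	Gm
LSU	2808	2503	m2A
LSU	2857	2552	Um
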