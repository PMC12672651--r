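subunit	position	type	plant_specific
SSU	1002	psi	FALSE
SSU	1345	psi	FALSE
SSU	1664	m4Cm	FALSE
SSU	1671	mC	FALSE
SSU	1807	m3U	FALSE
SSU	1827	m62A	FALSE
SSU	1828	m62A	FALSE
LSU	2055	m5C	FALSE
LSU	2221	psi	FALSE
LSU	2224	psi	FALSE
LSU	2229	psi	FALSE
LSU	2231	psi	FALSE
LSU	2257	m5U	FALSE
LSU	2338	m5U	FALSE
LSU	2499		TRUE
LSU	2560	Gm	FALSE
LSU	2808	m2A	FALSE
LSU	2857	Um	FALSE
LSU	2885	psi	FALSE
LSU	3010		FALSE
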