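subunit	position	type	plant_specific
SSU	761	mC	TRUE
SSU	1664	m4Cm	FALSE
SSU	1807		FALSE
SSU	1825	m2G	FALSE
SSU	1827	m62A	FALSE
SSU	1828	m62A	FALSE
LSU	905		FALSE
LSU	1212		TRUE
LSU	2030		FALSE
LSU	2188	psi	TRUE
LSU	2257	m5U	FALSE
LSU	2338		FALSE
LSU	2560	Gm	FALSE
LSU	2610	Gm	FALSE
LSU	2808	m2A	FALSE
LSU	2857	Um	FALSE
LSU	2885	psi	FALSE
LSU	3041		TRUE
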