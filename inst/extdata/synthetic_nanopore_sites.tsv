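subunit	position	type	plant_specific
SSU	540		TRUE
SSU	761		FALSE
SSU	1002	psi	FALSE
SSU	1113		TRUE
SSU	1345	psi	FALSE
SSU	1664		FALSE
SSU	1827		FALSE
SSU	1828		FALSE
LSU	2030		FALSE
LSU	2101		FALSE
LSU	2188		FALSE
LSU	2221	psi	FALSE
LSU	2224	psi	FALSE
LSU	2229	psi	FALSE
LSU	2231	psi	FALSE
LSU	2257		FALSE
LSU	2450		TRUE
LSU	2560		FALSE
LSU	2718		FALSE
LSU	2790		FALSE
LSU	2808		FALSE
LSU	2857		FALSE
LSU	2858		FALSE
LSU	2885	psi	FALSE
LSU	2901		TRUE
LSU	2960		FALSE
LSU	3100		FALSE
LSU	3155		FALSE
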