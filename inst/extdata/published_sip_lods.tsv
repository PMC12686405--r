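group	treatment	lod_ratio
Nitrosopelagicus_WCA	NH4_15N	3.82e-3
Nitrosopelagicus_WCA	UREA_15N	3.70e-3
Nitrosopelagicus_WCA	UREA_15N_PLUS_NH4	3.67e-3
Nitrosopumilus	NH4_15N	4.06e-3
Nitrosopumilus	UREA_15N	3.72e-3
Nitrosopumilus	UREA_15N_PLUS_NH4	3.72e-3
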