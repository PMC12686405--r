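region	treatment	lod_nM_d
Angola_Gyre	NH4_15N	0.017
Angola_Gyre	UREA_15N	0.040
Angola_Gyre	UREA_15N_PLUS_NH4_14N	0.146
Black_Sea	NH4_15N_10uM_O2	0.15
Black_Sea	NH4_15N_no_added_O2	0.17
Black_Sea	UREA_15N	0.06
Black_Sea	UREA_15N_PLUS_NH4_14N	0.17
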