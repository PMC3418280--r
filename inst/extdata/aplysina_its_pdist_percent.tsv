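taxon	A_gerardogreeni	A_revillagigedi	A_clathrata	A_fulva	A_fistularis_CAL	A_fistularis_BER	A_fistularis_BAH	A_archeri	A_cauliformis	A_insularis
A_gerardogreeni	0	0.719	0.719	1.295	1.727	1.439	1.727	1.727	1.727	1.871
A_revillagigedi	0.719	0	0.288	1.439	1.295	1.583	1.871	1.871	1.871	2.014
A_clathrata	0.719	0.288	0	1.439	1.007	1.583	1.871	1.871	1.871	2.014
A_fulva	1.295	1.439	1.439	0	1.583	0.144	0.432	0.432	1.007	0.576
A_fistularis_CAL	1.727	1.295	1.007	1.583	0	1.727	2.014	2.014	2.014	2.158
A_fistularis_BER	1.439	1.583	1.583	0.144	1.727	0	0.576	0.288	1.151	0.719
A_fistularis_BAH	1.727	1.871	1.871	0.432	2.014	0.576	0	0.863	1.439	1.007
A_archeri	1.727	1.871	1.871	0.432	2.014	0.288	0.863	0	1.439	1.007
A_cauliformis	1.727	1.871	1.871	1.007	2.014	1.151	1.439	1.439	0	1.583
A_insularis	1.871	2.014	2.014	0.576	2.158	0.719	1.007	1.007	1.583	0
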