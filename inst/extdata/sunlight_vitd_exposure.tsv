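snp	chromosome	gene	effect_allele	other_allele	eaf	beta	se	pval	n
rs3755967	4	GC	T	C	0.28	-0.089	0.0023	4.74E-343	79366
rs10741657	11	CYP2R1	A	G	0.40	0.031	0.0022	2.05E-46	79366
rs12785878	11	NADSYN1_DHCR7	T	G	0.75	0.036	0.0022	3.80E-62	79366
rs10745742	12	AMDHD1	T	C	0.40	0.017	0.0022	1.88E-14	79366
rs8018720	14	SEC23A	C	G	0.82	-0.017	0.0029	4.72E-09	79366
rs17216707	20	CYP24A1	T	C	0.79	0.026	0.0027	8.14E-23	79366
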