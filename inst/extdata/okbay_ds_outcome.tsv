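snp	effect_allele	other_allele	eaf	beta	se	pval	n
rs3755967	T	C	0.28	-0.001	0.004	0.731	161460
rs10741657	A	G	0.40	0.005	0.004	0.309	161460
rs12785878	T	G	0.75	0.006	0.005	0.215	161460
rs10745742	T	C	0.40	0.000	0.004	0.976	161460
rs8018720	C	G	0.82	0.001	0.005	0.780	161460
rs17216707	T	C	0.79	-0.004	0.004	0.340	161460
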