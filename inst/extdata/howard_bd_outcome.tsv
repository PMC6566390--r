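snp	effect_allele	other_allele	eaf	beta	se	pval	n
rs3755967	T	C	0.28	0.0012	0.0013	0.350	322580
rs10741657	A	G	0.40	0.002	0.001	0.055	322580
rs12785878	T	G	0.75	-0.002	0.001	0.287	322580
rs10745742	T	C	0.40	0.001	0.001	0.412	322580
rs8018720	C	G	0.82	0.0003	0.0015	0.857	322580
rs17216707	T	C	0.79	0.0003	0.0015	0.862	322580
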