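snp_id	risk_allele	other_allele	odds_ratio	risk_allele_freq	surrogate_id
rs10904849	A	G	1.08	0.32	rs10904850
rs35509282	T	C	1.11	0.11	rs11100443
rs4925386	C	T	1.07	0.69	rs11204472
rs10911251	A	C	1.06	0.56	rs6669796
rs1800469	T	C	1.09	0.31
rs174537	G	T	1.05	0.67
rs12241008	C	T	1.13	0.09
rs2423279	C	T	1.06	0.24
rs3184504	T	C	1.07	0.48
rs961253	A	C	1.08	0.36
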