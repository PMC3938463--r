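chr	region_lo_Mb	region_hi_Mb	phenotypes	lrs_max	size_Mb	n_genes	n_eqtls	n_cisqtls	n_cisqtgs
2	167.7	181.5	Collagen area; F-score	15.2	13.8	170	7	2	4
4	55.1	73.9	Hyp	17.4	17.9	123	6	6	13
5	3.1	20.1	Collagen area	18.1	17.0	103	8	1	1
5	82.8	103.9	Collagen area; Hyp	23.1	21.1	182	10	5	12
7	48.2	74.2	Collagen area; Hyp; F-score	20.3	26.0	396	9	7	34
12	60.5	73.3	Hyp	25.0	12.8	90	2	1	5
13	44.2	52.7	Collagen area; F-score	16.7	8.5	81	4	2	2
15	82.3	95.9	Collagen area; F-score	13.9	13.6	154	11	6	17
17	64.9	71.1	F-score	22.0	6.2	52	5	0	0
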