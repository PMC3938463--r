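phenotype	chr	lrs_max	snp_max	interval_lo_Mb	interval_hi_Mb	additive_effect	dataset
Collagen area	5	18.1	mCV23582150 - rs6392739	3.1	20.1	0.323	male/both
Collagen area	5	23.1	rs3678577 - rs6167407	85.1	97.9	0.451	female/both
Hyp	4	17.4	rs6254381 - rs13477745	55.1	73.9	58.957	female/both
Hyp	7	16.3	rs3703247 - rs8255275	52.8	56.7	56.761	female/both
Hyp	12	25.0	rs3716547 - rs13481511	60.5	73.3	-77.257	female/both
F-score	7	20.3	rs3703247 - rs8255275	48.2	53.7	0.562	male/both
F-score	17	22.0	rs13483077 - rs13483081	64.9	71.1	0.516	female
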