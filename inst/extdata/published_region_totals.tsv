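mean_size_Mb	n_genes	n_eqtls	n_cisqtls	n_cisqtgs
15.2	1351	68	30	85
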