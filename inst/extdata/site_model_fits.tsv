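model	neg_log_likelihood	n_free_params
M0	15044.66039	1
M7	15046.51687	2
M8	14963.64578	4
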