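species	n_clusters	n_clusters_gt2	cluster_genes	total_crps
sorghum	103	27	212	836
mei	74	31	189	584
peach	71	28	171	649
strawberry	73	15	203	518
tomato	113	35	316	875
poplar	103	42	351	892
cabbage	179	51	415	1570
grape	47	15	137	543
soybean	102	12	287	1256
maize	31	7	71	970
pear	84	35	303	786
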