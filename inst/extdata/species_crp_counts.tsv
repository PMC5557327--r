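species	proteome_crps	spada_crps
sorghum	327	509
mei	305	279
peach	294	355
strawberry	251	267
tomato	385	490
poplar	420	472
cabbage	560	1010
grape	180	363
soybean	583	673
maize	472	498
volvox	48	29
pear	385	401
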