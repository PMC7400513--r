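# Mixing pools: GC-MS sees one pool per metabolite, fed by the compartment
# pools with fitted fractional contributions (no net flux is carried).
pool	contributors
pyr_mix	pyr_c,pyr_m1,pyr_m2
mal_mix	mal_c,mal_m
cit_mix	cit_c,cit_m
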