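# Curated central-carbon metabolite table: glycolysis, oxidative PPP, TCA
# cycle with mitochondrial/cytosolic compartments, dual mitochondrial
# pyruvate pools, glutaminolysis and proline synthesis, plus mixing pools
# for metabolites whose GC-MS measurement cannot distinguish compartments.
id	compartment	carbons	symmetric	balanced
glc_e	extracellular	6	0	0
gln_e	extracellular	5	0	0
ser_e	extracellular	3	0	0
lac_e	extracellular	3	0	0
pyrx_e	extracellular	3	0	0
ala_e	extracellular	3	0	0
pro_e	extracellular	5	0	0
glux_e	extracellular	5	0	0
co2_x	extracellular	1	0	0
biomass_x	extracellular	0	0	0
hexp_c	cytosol	6	0	1
p5p_c	cytosol	5	0	1
s7p_c	cytosol	7	0	1
e4p_c	cytosol	4	0	1
gap_c	cytosol	3	0	1
pg3_c	cytosol	3	0	1
pep_c	cytosol	3	0	1
pyr_c	cytosol	3	0	1
ser_c	cytosol	3	0	1
pyr_m1	mitochondria	3	0	1
pyr_m2	mitochondria	3	0	1
accoa_m	mitochondria	2	0	1
oaa_m	mitochondria	4	0	1
cit_m	mitochondria	6	0	1
akg_m	mitochondria	5	0	1
suc_m	mitochondria	4	1	1
fum_m	mitochondria	4	1	1
mal_m	mitochondria	4	0	1
cit_c	cytosol	6	0	1
oaa_c	cytosol	4	0	1
accoa_c	cytosol	2	0	1
mal_c	cytosol	4	0	1
gln_c	cytosol	5	0	1
glu_m	mitochondria	5	0	1
pro_c	cytosol	5	0	1
pyr_mix	mixing	3	0	0
mal_mix	mixing	4	0	0
cit_mix	mixing	6	0	0
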