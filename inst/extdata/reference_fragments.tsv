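# Observed GC-MS fragments (TBDMS derivatives, [M-57]+ type ions) covering
# the metabolites reported in the labelling figures. Formulas are curated
# defaults for natural-abundance correction and are user-replaceable.
id	metabolite	carbons	formula
pyr	pyr_mix	1-3	C9H18NO3Si
pg3	pg3_c	1-3	C17H40O7PSi3
pep	pep_c	1-3	C14H30O6PSi2
fum	fum_m	1-4	C12H23O4Si2
akg	akg_m	1-5	C14H28NO5Si2
mal	mal_mix	1-4	C18H39O5Si3
pro	pro_c	1-5	C15H32NO2Si2
glu	glu_m	1-5	C19H42NO4Si3
gln	gln_c	1-5	C19H41N2O3Si3
cit	cit_mix	1-6	C26H55O7Si4
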