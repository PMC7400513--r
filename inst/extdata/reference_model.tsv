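# Curated reference network (fluxes in nmol/1e6 cells/h). Letter strings are
# carbon atom maps; the biomass drain is a lumped stoichiometric reaction
# whose coefficients (nmol per 1e6 cells of new biomass) are scaled for a
# dry cell weight of 514 pg/cell.
id	equation	reversible	lower	upper
HK	glc_e (abcdef) --> hexp_c (abcdef)	0	0	10000
PPP1	hexp_c (abcdef) --> p5p_c (bcdef) + co2_x (a)	0	0	10000
TK1	p5p_c (abcde) + p5p_c (fghij) --> s7p_c (abfghij) + gap_c (cde)	0	0	10000
TA	s7p_c (abcdefg) + gap_c (hij) --> hexp_c (abchij) + e4p_c (defg)	0	0	10000
TK2	p5p_c (abcde) + e4p_c (fghi) --> hexp_c (abfghi) + gap_c (cde)	0	0	10000
PFK	hexp_c (abcdef) --> gap_c (cba) + gap_c (def)	0	0	10000
GAPD	gap_c (abc) --> pg3_c (abc)	0	0	10000
ENO	pg3_c (abc) --> pep_c (abc)	0	0	10000
PK	pep_c (abc) --> pyr_c (abc)	0	0	10000
LDH	pyr_c (abc) --> lac_e (abc)	0	0	10000
PYRX	pyr_c (abc) --> pyrx_e (abc)	0	0	10000
SERUP	ser_e (abc) --> ser_c (abc)	0	0	10000
SERD	ser_c (abc) --> pyr_c (abc)	0	0	10000
MPC1	pyr_c (abc) --> pyr_m1 (abc)	0	0	10000
MPC2	pyr_c (abc) --> pyr_m2 (abc)	0	0	10000
PDH	pyr_m1 (abc) --> accoa_m (bc) + co2_x (a)	0	0	10000
PC	pyr_m2 (abc) + co2_x (d) --> oaa_m (abcd)	0	0	10000
ALAT	pyr_m2 (abc) --> ala_e (abc)	0	0	10000
ME	mal_c (abcd) --> pyr_c (abc) + co2_x (d)	0	0	10000
CS	oaa_m (abcd) + accoa_m (ef) --> cit_m (dcbfea)	0	0	10000
IDH	cit_m (abcdef) --> akg_m (abcde) + co2_x (f)	1	-10000	10000
AKGDH	akg_m (abcde) --> suc_m (bcde) + co2_x (a)	0	0	10000
SDH	suc_m (abcd) --> fum_m (abcd)	0	0	10000
FH	fum_m (abcd) --> mal_m (abcd)	1	-10000	10000
MDH	mal_m (abcd) --> oaa_m (abcd)	1	-10000	10000
CITL	cit_m (abcdef) --> cit_c (abcdef)	1	-10000	10000
ACL	cit_c (abcdef) --> oaa_c (fcba) + accoa_c (ed)	0	0	10000
MDHC	oaa_c (abcd) --> mal_c (abcd)	1	-10000	10000
MALT	mal_m (abcd) --> mal_c (abcd)	1	-10000	10000
GLNUP	gln_e (abcde) --> gln_c (abcde)	0	0	10000
GLS	gln_c (abcde) --> glu_m (abcde)	0	0	10000
GDH	glu_m (abcde) --> akg_m (abcde)	1	-10000	10000
GLUX	glu_m (abcde) --> glux_e (abcde)	0	0	10000
PROS	glu_m (abcde) --> pro_c (abcde)	0	0	10000
PROX	pro_c (abcde) --> pro_e (abcde)	0	0	10000
BIOMASS	51.4 hexp_c + 205.6 p5p_c + 300 accoa_c + 150 oaa_c + 114 glu_m + 50 gln_c + 90 pro_c + 300 ser_c --> biomass_x	0	0	10
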