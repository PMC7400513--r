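# Cofactor stoichiometry per unit net flux. NADH_m / NADH_c distinguish
# mitochondrial and cytosolic NADH; ATP rows are substrate-level
# phosphorylation (GTP from succinyl-CoA synthetase counted as ATP and
# lumped into AKGDH). Reactions without rows carry zero for every cofactor.
# The ledger counts explicit reaction-level ATP only; a growth-associated
# ATP demand can be added as a BIOMASS ATP row (nmol ATP per biomass unit).
reaction	cofactor	coefficient
HK	ATP	-1
PFK	ATP	-1
GAPD	NADH_c	1
GAPD	ATP	1
PK	ATP	1
LDH	NADH_c	-1
PPP1	NADPH	2
PDH	NADH_m	1
PC	ATP	-1
ME	NADPH	1
IDH	NADH_m	1
AKGDH	NADH_m	1
AKGDH	ATP	1
SDH	FADH2	1
MDH	NADH_m	1
MDHC	NADH_c	-1
ACL	ATP	-1
GDH	NADH_m	1
PROS	NADPH	-1
PROS	NADH_m	-1
PROS	ATP	-1
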