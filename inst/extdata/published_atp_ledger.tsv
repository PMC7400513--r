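# Published pathway-attributed ATP production fluxes (nmol/1e6 cells/h);
# inputs for the comparative ledger arithmetic.
pathway	parental	fhdim
Glycolysis	1161.3	1074.6
TCA cycle	1070.9	826.8
Total net	2215.3	1885.1
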