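# N-glycan composition classification rules, evaluated top to bottom;
# first matching row wins; empty bound = unbounded.
class	hexnac_min	hexnac_max	hex_min	hex_max	dhex_min	dhex_max	neuac_min	neuac_max
chitobiose_core		2	0	0
paucimannose	2	2	1	3			0	0
oligomannose	2	2	4		0	0	0	0
hybrid	3	3	5
complex	3
other
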