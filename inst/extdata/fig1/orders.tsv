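A	chr1	1	xa
A	chr1	2	a1
A	chr1	3	ya
B	chr1	1	xb
B	chr1	2	b1
B	chr1	3	yb
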