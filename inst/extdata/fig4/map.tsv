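a1	A
a2	A
b1	B
b2	B
c	C
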