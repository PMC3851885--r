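a1	A
b1	B
b2	B
b3	B
c1	C
c2	C
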