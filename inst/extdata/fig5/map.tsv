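m1	M
t1	T
s1	S
d1	Z
d2	Z
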