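a1	b2
a1	c1
a1	c2
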