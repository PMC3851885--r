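((((a1,b1)d1,b2)d2,c1)e1,(c2,b3)e2)e3;
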