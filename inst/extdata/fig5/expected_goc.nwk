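((d1,d2),(m1,(s1,t1)));
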