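(((a1,b1),(a2,b2))x,c);
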