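((enz01:0.15,enz02:0.15,enz03:0.15):0.3,(enz04:0.15,enz05:0.15,enz06:0.15):0.3,(enz07:0.15,enz08:0.15):0.3);
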