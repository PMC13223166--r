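variable,n00,n01,n10,n11
lateralization,254,110,109,181
nact,318,210,45,81
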