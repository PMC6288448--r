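species,sp1,sp2,sp3,sp4,sp5,sp6,sp7,sp8,sp9
sp1,0,0,1,0,0,0,0,1,0
sp2,0,0,1,0,0,0,0,1,0
sp3,0,0,1,0,0,0,0,1,0
sp4,0,0,1,0,0,0,0,1,0
sp5,0,0,1,0,0,0,0,1,0
sp6,0,0,1,0,0,0,0,1,0
sp7,0,0,1,0,0,0,0,1,0
sp8,0,0,1,0,0,0,0,1,0
sp9,0,0,1,0,0,0,0,1,0
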