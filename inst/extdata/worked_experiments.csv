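label,V0,R0,R1,dt_min,vector_per_donor,recipient_efficiency
transformation,83333333333.333328,2e6,1.9998e6,30,333,0.01
transduction,2.4e8,6e8,5.99999124e8,60,10,1
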