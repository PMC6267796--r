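segment,length_fraction,mass_fraction,com_ratio,gyration_ratio
hat,0.288,0.678,0.626,0.496
thigh,0.245,0.100,0.433,0.323
shank,0.246,0.0465,0.433,0.302
foot,0.152,0.0145,0.500,0.475
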