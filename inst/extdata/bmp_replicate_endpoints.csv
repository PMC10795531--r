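replicate,nml,ml_per_gvs,ml_per_gcod
R1,124,113,5.6
R2,143,130,6.5
R3,137,124,6.2
R4,142,129,6.1
R5,140,127,5.9
R6,130,118,6.3
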