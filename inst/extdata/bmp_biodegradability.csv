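replicate,ph_final,tcod_f_mg_l,cod_removal_pct
R1,7.5,16820,23.2
R2,7.65,15680,28.4
R3,7.61,16714,23.7
R4,7.6,16316,25.5
R5,7.58,16512,24.7
R6,7.75,16970,23.5
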