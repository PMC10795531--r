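variable,value
S_su,0.01
S_aa,0.001
S_fa,0.001
S_va,0.001
S_bu,0.001
S_pro,0.001
S_ac,0.001
S_h2,1.0e-8
S_ch4,1.0e-5
S_IC,0.04
S_IN,0.01
S_I,0.02
X_c,40.769
X_ch,0.00
X_pr,8.127
X_li,0.252
X_su,0.00
X_aa,0.01
X_fa,0.01
X_c4,0.01
X_pro,0.01
X_ac,0.01
X_h2,0.01
X_I,0.087
S_cat,0.04
S_an,0.10
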