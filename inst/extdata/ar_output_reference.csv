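variable,value
S_su,1.5031e-02
S_aa,6.7129e-03
S_fa,1.2853e-01
S_va,1.4532e-02
S_bu,1.6795e-02
S_pro,2.0244e-02
S_ac,4.2027e-02
S_h2,0.00
S_ch4,0.00
S_IC,6.3799e-01
S_IN,1.2453e-01
S_I,3.7066e+00
X_c,5.0183e+00
X_ch,4.9515e-02
X_pr,1.5778e-01
X_li,7.7605e-02
X_su,6.0868e-01
X_aa,1.4414e+00
X_fa,4.9932e-01
X_c4,5.2954e-01
X_pro,1.6868e-01
X_ac,1.0750e+00
X_h2,4.5639e-01
X_I,7.5005e+00
S_cat,0.04
S_an,0.10
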