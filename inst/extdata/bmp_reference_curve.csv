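day,ch4_measured_mean,ch4_simulated_ref
0,0,0.0000
1,46.9697,46.4013
2,71.2121,72.8888
3,87.5758,89.5668
4,98.4848,100.3918
5,106.3636,107.6856
6,114.5455,112.8359
7,120.0000,116.6777
8,122.5758,119.7153
9,123.6364,122.2534
10,123.6364,124.4768
11,123.6364,126.4973
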