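study,A,B,C,D
Anderson 1939,5,45,12,38
Garly 2006,2,42,5,32
Hogarth 1939,8,151,7,163
Karelitz 1954,0,175,1,80
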