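study,A,B,C,D
Anderson 1939,3,57,7,52
Garly 2006,1,43,2,35
Gibel 1942,0,195,0,180
Hogarth 1939,5,154,12,158
Karelitz 1951,1,85,0,38
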