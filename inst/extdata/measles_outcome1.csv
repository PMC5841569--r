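study,A,B,C,D
Karelitz 1954,1,155,12,69
Karelitz 1951,0,89,3,40
Garly 2006,1,43,6,32
Prasad 1967,13,64,27,53
Hogarth 1939,2,157,5,165
Anderson 1939,4,43,6,43
Gibel 1942,6,76,0,148
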