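study,treat,n,event
1,0,377,113
1,1,377,128
2,0,40,4
2,1,41,6
3,0,100,20
3,1,101,22
4,0,1010,201
4,1,1001,241
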