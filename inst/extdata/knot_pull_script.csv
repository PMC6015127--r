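time,particle,pull
0,1,0
1,1,0.01
2,1,0.02
3,1,0.03
4,1,0.04
0,2,0
1,2,0.01
2,2,0.02
3,2,0.03
4,2,0.04
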