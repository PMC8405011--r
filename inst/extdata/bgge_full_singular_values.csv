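component,lambda
1,46.56
2,16.46
3,9.91
4,5.40
5,2.13
6,0.86
7,0.42
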