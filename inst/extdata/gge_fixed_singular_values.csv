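component,lambda
1,47.04
2,17.72
3,11.8
4,8.85
5,6.79
6,4.53
7,2.70
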