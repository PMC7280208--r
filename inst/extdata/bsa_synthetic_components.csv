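j,weight_fraction
1,0.9409999999999999476
2,0.0400000000000000008
3,0.0129999999999999994
4,0.0060000000000000001
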