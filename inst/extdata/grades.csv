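lower,upper,label
0,0.2,Weakest
0.2,0.4,Weak
0.4,0.6,Medium
0.6,0.8,Strong
0.8,1,Strongest
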