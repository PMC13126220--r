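{"variables":["y1","y2","y3","y4","y5"],"moderators":["west"]}
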