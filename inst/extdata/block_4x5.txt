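00101
01100
10000
11011
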