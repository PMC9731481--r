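00101001
01100011
10000100
11011011
00111000
10100011
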