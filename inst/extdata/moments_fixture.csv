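33,34,42,33,28,42,25,36
22,29,22,31,27,38,23,24
19,31,182,179,224,198,28,23
20,40,160,190,205,175,21,32
21,21,169,186,157,166,29,32
37,29,35,18,31,41,19,27
33,47,26,21,28,23,29,16
28,34,31,40,40,28,32,42
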