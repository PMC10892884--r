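primer,bands,polymorphic
808,7,7
866,7,6
891,10,10
M11,8,7
M12,8,8
P12,5,5
P25,9,8
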