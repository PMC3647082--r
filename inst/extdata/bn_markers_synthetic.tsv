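slice_index	mass_kda
7	1236
15	720
21	480
31	242
38	146
49	66
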