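n00	1
n01	1
n02	1
n03	1
n04	1
n05	1
n06	2
n07	2
n08	2
n09	2
n10	2
n11	2
n12	3
n13	3
n14	3
n15	3
n16	3
n17	3
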