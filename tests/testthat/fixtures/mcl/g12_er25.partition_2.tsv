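n00	1
n01	2
n02	1
n03	3
n04	2
n05	2
n06	1
n07	2
n08	3
n09	2
n10	4
n11	2
n12	1
n13	2
n14	2
n15	2
n16	3
n17	3
n18	4
n19	2
n20	4
n21	1
n22	3
n23	2
n24	4
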