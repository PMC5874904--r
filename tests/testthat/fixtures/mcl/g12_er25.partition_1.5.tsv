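n00	1
n01	1
n02	1
n03	1
n04	1
n05	1
n06	1
n07	1
n08	1
n09	1
n10	1
n11	1
n12	1
n13	1
n14	1
n15	1
n16	1
n17	1
n18	1
n19	1
n20	1
n21	1
n22	1
n23	1
n24	1
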