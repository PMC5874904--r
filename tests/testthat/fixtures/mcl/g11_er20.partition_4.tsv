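n00	1
n01	2
n02	2
n03	3
n04	4
n05	5
n06	6
n07	7
n08	8
n09	9
n10	10
n11	5
n12	5
n13	8
n14	11
n15	12
n16	10
n17	13
n18	10
n19	14
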