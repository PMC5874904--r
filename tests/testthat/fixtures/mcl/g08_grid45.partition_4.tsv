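n00	1
n01	2
n02	3
n03	4
n04	5
n05	6
n06	7
n07	8
n08	9
n09	10
n10	11
n11	12
n12	13
n13	14
n14	15
n15	16
n16	17
n17	18
n18	19
n19	20
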