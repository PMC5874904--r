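n00	1
n01	2
n02	3
n03	4
n04	5
n05	6
n06	7
n07	2
n08	8
n09	2
n10	9
n11	10
n12	11
n13	2
n14	12
n15	13
n16	14
n17	15
n18	16
n19	17
n20	9
n21	3
n22	4
n23	2
n24	9
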