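n00	n03
n00	n04
n00	n12
n00	n21
n00	n22
n01	n07
n01	n09
n01	n23
n02	n21
n03	n16
n03	n22
n04	n07
n04	n15
n04	n17
n04	n19
n04	n21
n04	n23
n05	n07
n05	n11
n05	n13
n05	n14
n05	n18
n05	n20
n06	n14
n06	n17
n06	n21
n07	n09
n07	n11
n07	n12
n07	n13
n07	n14
n07	n15
n08	n15
n08	n16
n08	n18
n08	n21
n09	n21
n10	n11
n10	n20
n10	n22
n11	n13
n11	n19
n11	n23
n12	n19
n12	n20
n12	n21
n13	n15
n15	n20
n15	n23
n16	n17
n16	n18
n16	n22
n17	n22
n18	n20
n20	n22
n20	n24
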