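n00	n01
n00	n05
n01	n02
n01	n06
n02	n03
n02	n07
n03	n04
n03	n08
n04	n09
n05	n06
n05	n10
n06	n07
n06	n11
n07	n08
n07	n12
n08	n09
n08	n13
n09	n14
n10	n11
n10	n15
n11	n12
n11	n16
n12	n13
n12	n17
n13	n14
n13	n18
n14	n19
n15	n16
n16	n17
n17	n18
n18	n19
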