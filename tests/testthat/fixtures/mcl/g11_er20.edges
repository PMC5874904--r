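n00	n01
n00	n09
n00	n10
n00	n14
n01	n02
n01	n03
n01	n09
n01	n18
n02	n08
n03	n06
n03	n10
n04	n06
n04	n07
n04	n12
n05	n12
n06	n08
n07	n08
n07	n10
n07	n19
n08	n09
n08	n10
n08	n13
n08	n16
n08	n17
n08	n19
n09	n15
n09	n19
n10	n16
n10	n17
n10	n18
n11	n12
n12	n19
n14	n19
n15	n17
n16	n18
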