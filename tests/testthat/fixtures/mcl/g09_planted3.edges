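n00	n01
n00	n02
n00	n03
n00	n04
n00	n05
n00	n06
n01	n02
n01	n03
n01	n04
n01	n05
n02	n03
n02	n04
n02	n05
n02	n14
n03	n04
n03	n05
n04	n05
n06	n07
n06	n08
n06	n09
n06	n10
n06	n11
n07	n08
n07	n09
n07	n10
n07	n11
n07	n13
n08	n09
n08	n10
n08	n11
n09	n10
n09	n11
n10	n11
n12	n13
n12	n14
n12	n15
n12	n16
n12	n17
n13	n14
n13	n15
n13	n16
n13	n17
n14	n15
n14	n16
n14	n17
n15	n16
n15	n17
n16	n17
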