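n00	1
n01	1
n02	1
n03	2
n04	2
n05	2
n06	3
n07	3
n08	3
n09	4
n10	4
n11	4
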