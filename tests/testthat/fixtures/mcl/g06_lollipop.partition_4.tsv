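n00	1
n01	1
n02	1
n03	1
n04	1
n05	1
n06	2
n07	2
n08	3
n09	4
n10	4
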