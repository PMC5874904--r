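n00	1
n01	1
n02	1
n03	1
n04	2
n05	2
n06	3
n07	3
n08	3
n09	3
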