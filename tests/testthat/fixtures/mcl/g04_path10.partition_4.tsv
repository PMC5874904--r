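n00	1
n01	1
n02	2
n03	3
n04	4
n05	5
n06	6
n07	7
n08	8
n09	8
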