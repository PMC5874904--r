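n00	n01
n00	n02
n00	n03
n00	n04
n00	n05
n00	n06
n00	n07
n00	n08
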