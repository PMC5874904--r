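n00	n01
n00	n02
n00	n03
n00	n04
n01	n02
n01	n03
n01	n04
n02	n03
n02	n04
n03	n04
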