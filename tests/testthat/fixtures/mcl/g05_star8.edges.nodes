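n00
n01
n02
n03
n04
n05
n06
n07
n08
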