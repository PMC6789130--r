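bird_id,d15N,d13C
e1,12,-17
e2,13.1,-16.2
e3,11.4,-17.5
e4,12.7,-16.8
e5,13.5,-16
e6,11.9,-17.2
e7,12.3,-16.5
e8,13,-16.9
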