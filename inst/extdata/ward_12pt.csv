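bird_id,d15N,d13C
w01,11.2,-17.6
w02,11.8,-17.2
w03,12.1,-17.9
w04,11.5,-17.4
w05,12.4,-17.1
w06,11.9,-17.7
w07,14.2,-16.2
w08,14.8,-15.9
w09,14.5,-16.5
w10,15.1,-16.1
w11,13.9,-16.4
w12,14.6,-15.8
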