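hypothesis,expected_sign,parameter,std_error,effect_size
H1,+,0.12,0.074,0.010
H2,+,0.14,0.074,0.016
H3,+,-0.21,0.073,0.032
H4,+,0.18,0.073,0.041
H5,-,-0.10,0.075,0.015
H6,+,0.26,0.072,0.063
H7,+,0.33,0.071,0.109
H8,+,0.14,0.074,0.019
H9,+,0.69,0.066,0.479
H10,+,0.25,0.072,0.065
H11,+,0.20,0.073,0.040
H12,-,-0.12,0.074,0.021
H13,+,0.16,0.074,0.025
H14,+,-0.09,0.075,0.0008
H15,-,-0.21,0.073,0.043
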