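subsites:
  '-2': 7.0
  '-1': -4.5
  '1': 0.0
  '2': -1.1
  '3': -0.1
  '4': 0.9
rates:
  k_plus1:
    '2': 0.01
    '3': 0.1
    '4': 0.1
    '5': 0.09
    '6': 0.07
  k_minus1: 0.0
  k_plus2: 50.0
temperature_C: 30.0
enzyme_total_uM: 38.0
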