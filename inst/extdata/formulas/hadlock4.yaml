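# Hadlock four-parameter gestational-age estimation:
# GA weeks = 10.85 + 0.060*HC*FL + 0.670*BPD + 0.1680*AC, measurements in cm.
# Version 1.
name: hadlock4
transform: linear_ga_polynomial
native_unit: cm
ga_unit: weeks
required_inputs:
- bpd
- hc
- ac
- fl
coefficients:
  intercept: 10.85
  hc_fl: 0.060
  bpd: 0.670
  ac: 0.1680
ga_valid_range:
- 98.0
- 284.0
input_valid_ranges:
  bpd:
  - 12.0
  - 120.0
  hc:
  - 60.0
  - 400.0
  ac:
  - 40.0
  - 450.0
  fl:
  - 5.0
  - 95.0
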