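# Intergrowth-21st gestational-age estimation from head circumference and
# femur length: log(GA days) = 3.813 + 0.03243*log(HC)^2 + 0.001644*FL*log(HC),
# HC and FL in mm. Version 1.
name: intergrowth21_hcfl
transform: log_ga_polynomial
native_unit: mm
ga_unit: days
required_inputs:
- hc
- fl
coefficients:
  intercept: 3.813
  loghc2: 0.03243
  fl_loghc: 0.001644
ga_valid_range:
- 98.0
- 294.0
input_valid_ranges:
  hc:
  - 60.0
  - 400.0
  fl:
  - 5.0
  - 95.0
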