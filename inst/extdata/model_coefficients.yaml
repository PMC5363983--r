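# Coefficient tables for the Nitocra spinipes life-cycle model.
# All rates in d^-1, durations in d, ingestion in ug C per individual per day,
# bottom food concentration in ug C per cm^2, temperature in degrees Celsius.
version: 1
reference:
  temperature_C: 22.0
  bottom_concentration_ugC_cm2: 5.5
  calibrated_range_C: [15.0, 25.0]
carbon_per_cell_ug: 0.0000264
defaults:
  pN_DEV: {value: 0.129, alpha: 30.0}
  pC_DEV: {value: 0.111, alpha: 14.3}
  pL: {value: 0.308, alpha: 26.1}
  pE_DEV: {value: 0.315, alpha: 3.5}
  pBS: {value: 24.0, cv: 0.44}
  pNB: {value: 3.64, cv: 0.37}
  pS_NAU: {value: 0.00265}
  pS_COP: {value: 0.00483}
  pS_ADU: {value: 0.00319}
  p_female: {value: 0.5}
ingestion:
  # Holling type-III functional response: a_max * c^2 / (c^2 + k^2)
  nauplius: {a_max: 0.2981, k: 3.1993}
  copepodite: {a_max: 0.0677, k: 0.8491}
  adult: {a_max: 0.2623, k: 1.5053}
temperature:
  # duration-type rows give the rate as 1 / duration(t)
  pN_DEV:
    exp_decay: {type: exp_decay, a: 5.3676, b: 373.3086, c: 0.3027, factor: 5.85}
    belehradek: {type: belehradek, a: 250.0, t0: 7.2, b: -1.86, scale: 12.432, factor: 5.85}
  pC_DEV:
    exp_decay: {type: exp_decay, a: 7.9317, b: 43.4835, c: 0.1545, factor: 9.38}
    belehradek: {type: belehradek, a: 250.0, t0: 7.2, b: -1.86, scale: 19.956, factor: 9.38}
  pE_DEV:
    exp_decay: {type: exp_decay, a: 3.13, b: 70.612, c: 0.2899, factor: 3.25}
    belehradek: {type: belehradek, a: 250.0, t0: 7.2, b: -1.86, scale: 6.911, factor: 3.25}
  pL:
    belehradek: {type: belehradek, a: 250.0, t0: 7.2, b: -1.86, scale: 6.860, factor: 3.23}
  BS:
    quadratic: {type: quadratic, c0: -0.5569, c1: 4.0229, c2: -0.143, divisor: 1.0, factor: ~}
  pS_NAU:
    quadratic: {type: quadratic, c0: 8.3922, c1: -0.8520, c2: 0.0216, divisor: 100.0, factor: 975.0}
  pS_COP:
    quadratic: {type: quadratic, c0: 3.7204, c1: -0.3801, c2: 0.0110, divisor: 100.0, factor: 147.0}
  pS_ADU:
    quadratic: {type: quadratic, c0: 5.3501, c1: -0.5704, c2: 0.0157, divisor: 100.0, factor: 250.0}
food:
  pN_DEV: {type: power, c0: 0.0009, c1: 0.1789, c2: 0.1943, factor: 7.43, stage: nauplius}
  pC_DEV: {type: power, c0: 0.0002, c1: 0.1827, c2: 0.2824, factor: 11.8, stage: copepodite}
  BS: {type: exp_saturation, c0: 33.2374, c1: 10.626, factor: 0.0324, stage: adult}
  pS_NAU: {type: rational, c0: 25.3937, c1: 2972.583, factor: 690.0, stage: nauplius}
  pS_COP: {type: cubic, c0: 0.0016, c1: -0.0175, c2: 5.4615, c3: -73.4746, factor: 333.0, stage: copepodite}
  pS_ADU: {type: rational, c0: 12.8226, c1: 4504.1407, factor: 1111.0, stage: adult}
vessels:
  well96: {volume_mL: 0.27, bottom_area_cm2: 0.32}
  well24: {volume_mL: 2.0, bottom_area_cm2: 1.9}
  well6: {volume_mL: 8.0, bottom_area_cm2: 9.6}
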