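# Transcribed experimental summaries for the Nitocra spinipes
# temperature (15/20/25 C at 2.5e5 cells/mL) and food (0 .. 5e5 cells/mL
# at 22 C) life-cycle tests: measured temperatures, development-time and
# brood-size summaries, alive/dead and female/male counts, and the
# simulated-vs-theoretical reproduction comparison.
version: 1
measured_temperatures:
  # mean of daily means per temperature setup [degC]
  "15C": {mean: 14.86, min: 13.6, max: 17.3}
  "20C": {mean: 19.34, min: 18.3, max: 20.2}
  "25C": {mean: 24.90, min: 24.0, max: 25.2}
development_summaries:
  # mean, sd, n per endpoint
  "15C":
    naupliar: {mean: 9.52, sd: 2.19, n: 61}
    copepodite: {mean: 12.31, sd: 2.04, n: 55}
    dc_dn: 1.29
    embryonic: {mean: 4.08, sd: 0.36, n: 37}
    brood_size: {mean: 27.65, sd: 6.59, n: 34}
  "20C":
    naupliar: {mean: 6.44, sd: 0.66, n: 66}
    copepodite: {mean: 10.12, sd: 2.89, n: 65}
    dc_dn: 1.57
    embryonic: {mean: 3.39, sd: 0.76, n: 136}
    brood_size: {mean: 23.76, sd: 10.78, n: 139}
  "25C":
    naupliar: {mean: 5.57, sd: 1.18, n: 60}
    copepodite: {mean: 8.86, sd: 1.29, n: 57}
    dc_dn: 1.59
    embryonic: {mean: 3.18, sd: 0.87, n: 11}
    brood_size: {mean: 10.95, sd: 4.94, n: 43}
  "food_1.25e4":
    naupliar: {mean: 16.10, sd: 3.73, n: 20}
    copepodite: {mean: 20.50, sd: 6.81, n: 4}
    dc_dn: 1.27
  "food_2.5e4":
    naupliar: {mean: 12.86, sd: 1.80, n: 28}
    copepodite: {mean: 17.52, sd: 9.64, n: 21}
    dc_dn: 1.36
    brood_size: {mean: 12.0, sd: 2.55, n: 5}
  "food_5e4":
    naupliar: {mean: 11.74, sd: 2.69, n: 31}
    copepodite: {mean: 13.32, sd: 4.36, n: 28}
    dc_dn: 1.13
    brood_size: {mean: 20.50, sd: 10.77, n: 40}
  "food_1.25e5":
    naupliar: {mean: 8.51, sd: 1.29, n: 34}
    copepodite: {mean: 12.55, sd: 4.85, n: 32}
    dc_dn: 1.47
    brood_size: {mean: 25.88, sd: 9.26, n: 51}
  "food_2.5e5":
    naupliar: {mean: 7.66, sd: 1.44, n: 34}
    copepodite: {mean: 11.50, sd: 3.32, n: 31}
    dc_dn: 1.50
    brood_size: {mean: 30.50, sd: 9.91, n: 52}
  "food_5e5":
    naupliar: {mean: 6.71, sd: 0.50, n: 35}
    copepodite: {mean: 11.21, sd: 2.37, n: 34}
    dc_dn: 1.67
    brood_size: {mean: 35.35, sd: 7.59, n: 49}
contingency:
  # r x 2 alive/dead and female/male counts; one row per treatment.
  # reported_p is the p-value printed alongside each comparison.
  temperature-sexratio:
    columns: [female, male]
    rows: ["15C", "20C", "25C"]
    counts: [[22, 31], [39, 24], [40, 10]]
    reported_p: 0.00033
  temperature-copepodite-mortality:
    columns: [alive, dead]
    rows: ["15C", "20C", "25C"]
    counts: [[55, 6], [65, 0], [57, 3]]
    reported_p: 0.037
  temperature-naupliar-mortality:
    columns: [alive, dead]
    rows: ["15C", "20C", "25C"]
    counts: [[61, 5], [66, 3], [60, 9]]
    reported_p: 0.17
  food-naupliar-mortality:
    columns: [alive, dead]
    rows: ["1.25e4", "2.5e4", "5e4", "1.25e5", "2.5e5", "5e5"]
    counts: [[19, 17], [28, 8], [34, 2], [35, 1], [34, 2], [35, 1]]
    reported_p: 0.0000000098
  food-copepodite-mortality:
    columns: [alive, dead]
    rows: ["1.25e4", "2.5e4", "5e4", "1.25e5", "2.5e5", "5e5"]
    counts: [[10, 9], [24, 4], [32, 2], [33, 2], [32, 2], [35, 0]]
    reported_p: 0.0000015
  food-sexratio:
    columns: [female, male]
    rows: ["1.25e4", "2.5e4", "5e4", "1.25e5", "2.5e5", "5e5"]
    counts: [[0, 3], [4, 17], [3, 25], [10, 21], [8, 23], [11, 23]]
    reported_p: 0.29
reproduction_comparison:
  # simulated (mean, sd, n) vs theoretical values for the reproduction test
  "15C":
    period: {mean: 3.96, sd: 0.79, n: 50, theoretical: 4.04}
    brood_size: {mean: 29.30, sd: 13.74, n: 50, theoretical: 27.64}
  "20C":
    period: {mean: 3.33, sd: 0.72, n: 50, theoretical: 3.39}
    brood_size: {mean: 26.10, sd: 10.97, n: 50, theoretical: 23.82}
  "25C":
    period: {mean: 3.21, sd: 0.58, n: 50, theoretical: 3.18}
    brood_size: {mean: 10.74, sd: 5.16, n: 50, theoretical: 10.70}
  "food_2.5e4":
    brood_size: {mean: 11.26, sd: 3.57, n: 50, theoretical: 11.13}
  "food_5e4":
    brood_size: {mean: 21.48, sd: 10.31, n: 50, theoretical: 22.51}
  "food_1.25e5":
    brood_size: {mean: 31.00, sd: 12.27, n: 50, theoretical: 29.49}
  "food_2.5e5":
    brood_size: {mean: 31.32, sd: 12.99, n: 50, theoretical: 30.58}
  "food_5e5":
    brood_size: {mean: 26.92, sd: 15.75, n: 50, theoretical: 31.11}
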