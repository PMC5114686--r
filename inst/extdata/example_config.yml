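# Machine-readable analysis plan for a threshold-crossing development
# program on a synthetic normal endpoint.
estimand:
  population: "synthetic treatment-eligible population"
  variable: "continuous response at week 24 (endpoint units)"
  effect_measure: "mean difference versus historical control"

design:
  delta: 0.2      # standardized effect the program is powered for
  sigma: 1.0      # planning standard deviation (endpoint units)
  alpha: 0.025    # one-sided significance level
  power: 0.80

rules: ["naive", "ci", "ci+0.1", "ci+0.2", "ci+0.3"]

historical:
  csv: "example_cohorts.csv"

pooling:
  method: "random"

grid:
  n_h: [100, 250, 500, 1000]
  drift: [0.0, 0.1]

reps_null: 100000
reps_power: 10000

flow:
  rule: "ci"
  n_h: 1000
  stage2: "rct"
  futility: "historical_mean"
  true_delta: [0.0, 0.2]
  reps: 10000

seed: 1
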