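# The full simulation grid: six size designs crossed with the variance,
# correlation and generation-mode factors (216 scenarios). Large-study
# sizes under the imbalanced designs are 357, 98 and 588 respectively.
sizes:
  - [5, 500, balanced]
  - [15, 500, balanced]
  - [15, 3000, balanced]
  - [5, 500, imbalanced]
  - [15, 500, imbalanced]
  - [15, 3000, imbalanced]
tau0_sq: [0.05, 1, 4]
tau1_sq: [0.05, 1, 4]
rho: [0, 0.5]
generation_mode: [random_intercept, stratified_intercept]
beta0: -0.85
beta1: 0.18
n_reps: 1000
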